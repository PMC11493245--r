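#' Match and trim the inline transposon tag
#'
#' Keeps reads whose leading `nchar(tag)` bases match the tag with at most
#' `max_mismatches` substitutions and removes the tag from them; all other
#' reads are discarded. Kept/discarded counts are attached as attributes
#' `kept` and `discarded`.
#'
#' @param reads a `read_set`.
#' @param tag the transposon tag (non-empty DNA string).
#' @param max_mismatches maximum tolerated mismatches within the tag.
#' @return a `read_set` of trimmed reads.
#' @export
match_and_trim_tag <- function(reads, tag, max_mismatches = 0L) {
  stopifnot(inherits(reads, "read_set"))
  tlen <- nchar(tag)
  if (tlen == 0) stop("tag must be non-empty")
  if (length(reads$seq) && any(nchar(reads$seq) < tlen))
    stop("tag longer than reads")
  if (length(reads$seq) == 0) {
    out <- read_set(character(0), character(0), character(0), tag = tag)
    attr(out, "kept") <- 0L; attr(out, "discarded") <- 0L
    return(out)
  }
  prefix <- substr(reads$seq, 1L, tlen)
  if (max_mismatches == 0) {
    ok <- prefix == tag
  } else {
    pm <- matrix(unlist(strsplit(prefix, "", fixed = TRUE)), nrow = tlen)
    mm <- colSums(pm != strsplit(tag, "", fixed = TRUE)[[1]])
    ok <- mm <= max_mismatches
  }
  out <- read_set(reads$id[ok],
                  substr(reads$seq[ok], tlen + 1L, nchar(reads$seq[ok])),
                  substr(reads$qual[ok], tlen + 1L, nchar(reads$qual[ok])),
                  tag = tag, error_rate = attr(reads, "error_rate"))
  attr(out, "kept") <- sum(ok)
  attr(out, "discarded") <- sum(!ok)
  out
}

# k-mer index of junction seeds over both strands of every replicon.
# Key convention mirrors read synthesis: the seed observed in a read from an
# insertion at position p is ref[p, p+k) on '+', revcomp(ref[p-k+1, p]) on '-'.
build_seed_index <- function(ref, seed_length) {
  if (length(ref$seqs) == 0) stop("empty reference index")
  kmer <- character(0); pos <- integer(0); strand <- character(0)
  replicon <- character(0)
  for (rn in names(ref$seqs)) {
    refstr <- as.character(ref$seqs[[rn]])
    L <- nchar(refstr)
    circ <- ref$circular[[rn]]
    p_fwd <- if (circ) 0:(L - 1L) else 0:(L - seed_length)
    k_fwd <- extract_windows(refstr, p_fwd, seed_length, circ)
    p_rev <- if (circ) 0:(L - 1L) else (seed_length - 1L):(L - 1L)
    k_rev <- revcomp_chr(extract_windows(refstr, p_rev - seed_length + 1L,
                                         seed_length, circ))
    kmer <- c(kmer, k_fwd, k_rev)
    pos <- c(pos, p_fwd, p_rev)
    strand <- c(strand, rep("+", length(p_fwd)), rep("-", length(p_rev)))
    replicon <- c(replicon, rep(rn, length(p_fwd) + length(p_rev)))
  }
  dup <- kmer %in% kmer[duplicated(kmer)]
  list(kmer = kmer[!dup], pos = pos[!dup], strand = strand[!dup],
       replicon = replicon[!dup], ambiguous = unique(kmer[dup]))
}

#' Map trimmed junction reads to insertion sites
#'
#' Locates each read's leading `seed_length` bases in the reference by exact
#' match over both strands (circular replicons wrap). A seed matching a unique
#' locus yields an insertion site at the junction base on the matched strand;
#' reads whose seed occurs at two or more loci are discarded as ambiguous,
#' unmatched seeds are discarded as unmapped. Counts are attached as
#' attributes `mapped`, `ambiguous` and `unmapped`.
#'
#' @param trimmed a `read_set` with the tag already removed.
#' @param ref a `ref_assembly`.
#' @param seed_length exact-match seed length (post-tag reads must be at
#'   least this long).
#' @param label library label to record on the site set.
#' @return a data.frame of class `insertion_sites` with columns `replicon`,
#'   `position`, `strand`, `read_count` (unique site keys).
#' @export
map_insertions <- function(trimmed, ref, seed_length = 25L,
                           label = c("input", "output")) {
  stopifnot(inherits(trimmed, "read_set"))
  label <- match.arg(label)
  if (length(trimmed$seq) && any(nchar(trimmed$seq) < seed_length))
    stop("post-tag read length shorter than seed_length")
  idx <- build_seed_index(ref, seed_length)
  seeds <- substr(trimmed$seq, 1L, seed_length)
  amb <- seeds %in% idx$ambiguous
  m <- match(seeds, idx$kmer)
  ok <- !amb & !is.na(m)
  m <- m[ok]
  key <- paste(idx$replicon[m], idx$pos[m], idx$strand[m], sep = "\r")
  tab <- table(key)
  first <- !duplicated(key)
  df <- data.frame(replicon = idx$replicon[m][first],
                   position = idx$pos[m][first],
                   strand = idx$strand[m][first],
                   read_count = as.integer(tab[key[first]]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$replicon, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, mapped = sum(ok), ambiguous = sum(amb),
            unmapped = sum(!amb & is.na(match(seeds, idx$kmer))),
            class = c("insertion_sites", "data.frame"))
}

#' Insertion site set from a library (identity mapping)
#'
#' Converts an `insertion_library` directly to an `insertion_sites` table,
#' bypassing read synthesis and mapping. Useful for scoring simulations
#' without the sequencing layer.
#'
#' @param lib an `insertion_library`.
#' @return an `insertion_sites` data.frame.
#' @export
sites_from_library <- function(lib) {
  structure(data.frame(replicon = lib$replicon, position = lib$position,
                       strand = lib$strand,
                       read_count = as.integer(lib$abundance),
                       stringsAsFactors = FALSE),
            label = library_label(lib),
            class = c("insertion_sites", "data.frame"))
}

#' Per-gene insertion indices
#'
#' For each annotated gene, counts the distinct insertion site keys whose
#' position falls inside the gene (strand-specific sites are distinct), and
#' computes the insertion index: unique sites per bp of gene, divided by the
#' library-wide total of unique sites so indices are comparable across
#' libraries sequenced or selected to different depths.
#'
#' @param sites an `insertion_sites` table.
#' @param annotation gene annotation data.frame.
#' @return a data.frame of class `insertion_index_table` with columns
#'   `gene_id`, `replicon`, `start`, `end`, `length`, `unique_sites`,
#'   `raw_density`, `insertion_index`.
#' @export
compute_insertion_index <- function(sites, annotation) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0) stop("annotation must be non-empty")
  total <- nrow(sites)
  gene <- locate_in_genes(sites$replicon, sites$position, annotation)
  counts <- table(factor(gene, levels = annotation$gene_id))
  len <- annotation$end - annotation$start
  raw <- as.integer(counts) / len
  structure(data.frame(gene_id = annotation$gene_id,
                       replicon = annotation$replicon,
                       start = annotation$start, end = annotation$end,
                       length = len,
                       unique_sites = as.integer(counts),
                       raw_density = raw,
                       insertion_index = if (total > 0) raw / total else
                         rep(0, length(raw)),
                       stringsAsFactors = FALSE),
            label = attr(sites, "label"),
            total_unique_sites = total,
            class = c("insertion_index_table", "data.frame"))
}

#' Call candidate genes by output/input insertion-index ratio
#'
#' The score for gene g is `R_g = (output_index + pc) / (input_index + pc)`;
#' genes with `R_g` above the (deliberately arbitrary) threshold are flagged
#' as candidates. By default the pseudocount `pc` is half the smallest
#' nonzero normalized index across the two libraries, which avoids division
#' by zero while preserving the ranking of observed indices. Genes missing
#' from one table are treated as index 0 and flagged in the `missing` column.
#'
#' @param input_idx,output_idx `insertion_index_table`s over the same genes.
#' @param threshold candidate-calling cutoff on the ratio (default 5).
#' @param pseudocount numeric pseudocount; `NULL` for the data-driven default.
#' @return a data.frame of class `candidate_table`, sorted by gene coordinate,
#'   with columns `gene_id`, `replicon`, `start`, `end`, `input_index`,
#'   `output_index`, `ratio`, `candidate`, `missing`; the threshold and
#'   pseudocount used are attached as attributes.
#' @export
call_candidates <- function(input_idx, output_idx, threshold = 5,
                            pseudocount = NULL) {
  genes <- unique(rbind(input_idx[c("gene_id", "replicon", "start", "end")],
                        output_idx[c("gene_id", "replicon", "start", "end")]))
  mi <- match(genes$gene_id, input_idx$gene_id)
  mo <- match(genes$gene_id, output_idx$gene_id)
  inp <- ifelse(is.na(mi), 0, input_idx$insertion_index[mi])
  out <- ifelse(is.na(mo), 0, output_idx$insertion_index[mo])
  if (is.null(pseudocount)) {
    nz <- c(inp[inp > 0], out[out > 0])
    pseudocount <- if (length(nz)) min(nz) / 2 else 0
  }
  denom <- inp + pseudocount
  ratio <- ifelse(denom > 0, (out + pseudocount) / denom, NA_real_)
  df <- data.frame(genes, input_index = inp, output_index = out,
                   ratio = ratio, candidate = !is.na(ratio) & ratio > threshold,
                   missing = is.na(mi) | is.na(mo),
                   stringsAsFactors = FALSE)
  df <- df[order(df$replicon, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, threshold = threshold, pseudocount = pseudocount,
            class = c("candidate_table", "data.frame"))
}

#' Run the full screen from reads to candidates
#'
#' Convenience wrapper: tag trimming, junction mapping and index computation
#' for the input and output read sets, then candidate calling.
#'
#' @param input_reads,output_reads `read_set`s for the two libraries.
#' @param ref a `ref_assembly`.
#' @param annotation gene annotation data.frame.
#' @param tag transposon tag.
#' @param max_mismatches tag mismatch tolerance.
#' @param seed_length mapping seed length.
#' @param threshold,pseudocount passed to [call_candidates()].
#' @return a list with `input_sites`, `output_sites`, `input_index`,
#'   `output_index`, `candidates`, and a `log` of read-fate counts.
#' @export
run_screen <- function(input_reads, output_reads, ref, annotation,
                       tag, max_mismatches = 0L, seed_length = 25L,
                       threshold = 5, pseudocount = NULL) {
  tin <- match_and_trim_tag(input_reads, tag, max_mismatches)
  tout <- match_and_trim_tag(output_reads, tag, max_mismatches)
  sin <- map_insertions(tin, ref, seed_length, label = "input")
  sout <- map_insertions(tout, ref, seed_length, label = "output")
  iin <- compute_insertion_index(sin, annotation)
  iout <- compute_insertion_index(sout, annotation)
  cand <- call_candidates(iin, iout, threshold, pseudocount)
  list(input_sites = sin, output_sites = sout,
       input_index = iin, output_index = iout, candidates = cand,
       log = data.frame(
         library = c("input", "output"),
         kept = c(attr(tin, "kept"), attr(tout, "kept")),
         tag_discarded = c(attr(tin, "discarded"), attr(tout, "discarded")),
         mapped = c(attr(sin, "mapped"), attr(sout, "mapped")),
         ambiguous = c(attr(sin, "ambiguous"), attr(sout, "ambiguous")),
         unmapped = c(attr(sin, "unmapped"), attr(sout, "unmapped"))))
}

#' Write an insertion site set as a bedgraph-like TSV
#' @param sites an `insertion_sites` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a candidate table as TSV
#' @param candidates a `candidate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  write.table(as.data.frame(candidates), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
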