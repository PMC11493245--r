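#' Generate a synthetic multi-replicon reference with gene annotation
#'
#' Builds a two-replicon assembly (a "chromosome" and a smaller "plasmid",
#' both circular) with non-overlapping genes of random length separated by
#' fixed-length intergenic spacers. The layout mirrors a conjugative-plasmid
#' host: a fraction of the genes is placed on the plasmid, the rest on the
#' chromosome. Coordinates are 0-based half-open internally; [write_gff3()]
#' converts to the 1-based inclusive convention on disk.
#'
#' @param n_genes total number of genes to draw (>= 0).
#' @param gene_length_range length-2 integer vector, inclusive range (bp) from
#'   which gene lengths are drawn uniformly.
#' @param intergenic_length fixed spacer length (bp) placed before, between and
#'   after genes on each replicon.
#' @param plasmid_fraction proportion of genes assigned to the plasmid
#'   replicon (rounded; the remainder goes to the chromosome).
#' @param seed integer seed; the same seed yields byte-identical FASTA/GFF3.
#'
#' @return a list with components
#'   \describe{
#'     \item{assembly}{a `ref_assembly`: list of `seqs`
#'       ([Biostrings::DNAStringSet]) and `circular` (named logical).}
#'     \item{annotation}{a data.frame with columns `gene_id`, `replicon`,
#'       `start`, `end` (0-based half-open), `strand`.}
#'   }
#' @export
generate_reference <- function(n_genes,
                               gene_length_range = c(300L, 900L),
                               intergenic_length = 200L,
                               plasmid_fraction = 0.2,
                               seed = 1L) {
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (any(gene_length_range <= 0) || intergenic_length <= 0)
    stop("gene and intergenic lengths must be positive")
  if (gene_length_range[1] > gene_length_range[2])
    stop("gene_length_range must be increasing")
  if (plasmid_fraction < 0 || plasmid_fraction > 1)
    stop("plasmid_fraction must be in [0, 1]")
  set.seed(seed)

  n_plasmid <- as.integer(round(n_genes * plasmid_fraction))
  n_chrom <- n_genes - n_plasmid
  counts <- c(chromosome = n_chrom, plasmid = n_plasmid)

  seqs <- character(0)
  ann <- list()
  gene_no <- 0L
  for (rep_name in names(counts)) {
    k <- counts[[rep_name]]
    glens <- if (k > 0)
      sample(seq(gene_length_range[1], gene_length_range[2]), k, replace = TRUE)
    else integer(0)
    total_len <- intergenic_length * (k + 1L) + sum(glens)
    bases <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
    seqs[[rep_name]] <- paste(bases, collapse = "")
    pos <- intergenic_length
    for (i in seq_len(k)) {
      gene_no <- gene_no + 1L
      ann[[gene_no]] <- data.frame(
        gene_id = sprintf("gene%03d", gene_no),
        replicon = rep_name,
        start = pos,
        end = pos + glens[i],
        strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE
      )
      pos <- pos + glens[i] + intergenic_length
    }
  }

  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(0), replicon = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  assembly <- ref_assembly(
    Biostrings::DNAStringSet(unlist(seqs)),
    circular = setNames(rep(TRUE, length(seqs)), names(seqs))
  )
  list(assembly = assembly, annotation = annotation)
}

#' Construct a reference assembly container
#'
#' @param seqs a [Biostrings::DNAStringSet] of replicon sequences with unique
#'   names; alphabet restricted to A/C/G/T.
#' @param circular logical vector (one per replicon) of circularity flags.
#' @return an object of class `ref_assembly`.
#' @export
ref_assembly <- function(seqs, circular) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("replicon names must be present and unique")
  if (any(Biostrings::width(seqs) == 0)) stop("replicon sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(seqs)
  if (any(rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE]) !=
          Biostrings::width(seqs)))
    stop("replicon alphabet must be A/C/G/T only")
  if (length(circular) != length(seqs)) stop("one circularity flag per replicon")
  names(circular) <- names(seqs)
  structure(list(seqs = seqs, circular = circular), class = "ref_assembly")
}

#' @export
print.ref_assembly <- function(x, ...) {
  cat(sprintf("ref_assembly with %d replicon(s):\n", length(x$seqs)))
  for (n in names(x$seqs))
    cat(sprintf("  %s: %d bp (%s)\n", n, Biostrings::width(x$seqs[n]),
                if (x$circular[[n]]) "circular" else "linear"))
  invisible(x)
}

#' Replicon lengths of a reference assembly
#' @param ref a `ref_assembly`.
#' @return named integer vector of replicon lengths (bp).
#' @export
replicon_lengths <- function(ref) {
  setNames(Biostrings::width(ref$seqs), names(ref$seqs))
}

validate_annotation <- function(annotation, ref = NULL) {
  stopifnot(all(c("gene_id", "replicon", "start", "end", "strand") %in%
                  names(annotation)))
  if (anyDuplicated(annotation$gene_id)) stop("gene_ids must be unique")
  if (any(annotation$start < 0) || any(annotation$start >= annotation$end))
    stop("gene intervals must satisfy 0 <= start < end")
  if (!is.null(ref)) {
    lens <- replicon_lengths(ref)
    if (!all(annotation$replicon %in% names(lens)))
      stop("annotation refers to unknown replicon(s)")
    if (any(annotation$end > lens[annotation$replicon]))
      stop("gene interval exceeds replicon length")
  }
  invisible(annotation)
}

#' Write a reference assembly to FASTA
#'
#' @param ref a `ref_assembly`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref$seqs, path)
  invisible(path)
}

#' Read a reference assembly from FASTA
#'
#' @param path FASTA path.
#' @param circular logical circularity flags, recycled over replicons.
#' @return a `ref_assembly`.
#' @export
read_reference_fasta <- function(path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  ref_assembly(seqs, rep_len(circular, length(seqs)))
}

#' Write gene annotation to GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
#' inclusive, so `start` becomes `start + 1` and `end` is unchanged.
#'
#' @param annotation annotation data.frame (see [generate_reference()]).
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  validate_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$source <- "conjscreen"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 path.
#' @param feature feature type to keep (default "gene").
#' @return annotation data.frame in the package's 0-based half-open convention.
#' @export
read_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% feature]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- sprintf("gene%03d", seq_along(gr))
  data.frame(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
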