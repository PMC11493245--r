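#' Construct a read set
#'
#' A lightweight container for single-end junction reads: parallel character
#' vectors of ids, bases and Sanger-encoded qualities, plus the declared read
#' structure (inline transposon tag at the 5' end, followed by genomic
#' sequence starting at the insertion junction).
#'
#' @param id,seq,qual equal-length character vectors.
#' @param tag the inline transposon tag the reads were built with.
#' @param error_rate the per-base substitution rate used at synthesis.
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual, tag = "", error_rate = 0) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)),
            tag = tag, error_rate = error_rate, class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, tag '%s'\n", length(x$seq), attr(x, "tag")))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)

# extract windows [start0, start0+len) from a replicon (0-based), vectorized;
# circular replicons wrap, linear windows running off either end return NA
extract_windows <- function(refstr, start0, len, circular) {
  L <- nchar(refstr)
  if (circular) {
    s <- ((start0 %% L) + L) %% L
    doubled <- paste0(refstr, substr(refstr, 1L, min(L, len)))
    out <- substring(doubled, s + 1L, s + len)
    # windows longer than L would need more wrapping; disallow
    if (len > L) stop("read window longer than circular replicon")
    out
  } else {
    ok <- start0 >= 0 & (start0 + len) <= L
    out <- rep(NA_character_, length(start0))
    if (any(ok)) out[ok] <- substring(refstr, start0[ok] + 1L, start0[ok] + len)
    out
  }
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Synthesize transposon-junction reads from an insertion library
#'
#' Emulates single-end sequencing of transposon-genome junctions: each read is
#' the inline transposon `tag` followed by genomic sequence starting at the
#' insertion point and extending 3'-ward on the insertion's strand. On the
#' `+` strand the genomic part is the reference from the junction position
#' forward; on the `-` strand it is the reverse complement of the window
#' ending at the junction position. Circular replicons wrap past their ends;
#' reads that would run off a linear replicon are discarded (counted in the
#' `discarded_overrun` attribute). Substitution errors are applied i.i.d. per
#' base over the whole read (tag included) at `error_rate`; qualities are a
#' constant Sanger 'I' (Q40).
#'
#' @param lib an `insertion_library`.
#' @param ref a `ref_assembly`.
#' @param tag inline transposon tag (DNA string, non-empty).
#' @param read_length total read length including the tag.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param depth_per_mutant reads emitted per mutant.
#' @param seed integer seed.
#' @return a `read_set`.
#' @export
synthesize_reads <- function(lib, ref, tag = "TAAGAGACAG", read_length = 50L,
                             error_rate = 0, depth_per_mutant = 10L,
                             seed = 1L) {
  stopifnot(inherits(lib, "insertion_library"))
  if (nchar(tag) == 0 || read_length <= nchar(tag))
    stop("read_length must exceed tag length and tag must be non-empty")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  set.seed(seed)
  glen <- read_length - nchar(tag)

  n_reads <- as.integer(lib$abundance) * as.integer(depth_per_mutant)
  rep_idx <- rep.int(seq_len(nrow(lib)), n_reads)
  replicon <- lib$replicon[rep_idx]
  position <- lib$position[rep_idx]
  strand <- lib$strand[rep_idx]

  genomic <- rep(NA_character_, length(rep_idx))
  for (rn in unique(replicon)) {
    sel <- replicon == rn
    refstr <- as.character(ref$seqs[[rn]])
    circ <- ref$circular[[rn]]
    fwd <- sel & strand == "+"
    rev <- sel & strand == "-"
    if (any(fwd)) genomic[fwd] <- extract_windows(refstr, position[fwd], glen, circ)
    if (any(rev)) {
      win <- extract_windows(refstr, position[rev] - glen + 1L, glen, circ)
      ok <- !is.na(win)
      rc <- rep(NA_character_, length(win))
      if (any(ok)) rc[ok] <- revcomp_chr(win[ok])
      genomic[rev] <- rc
    }
  }
  keep <- !is.na(genomic)
  discarded <- sum(!keep)
  if (!any(keep)) {
    rs <- read_set(character(0), character(0), character(0),
                   tag = tag, error_rate = error_rate)
    attr(rs, "discarded_overrun") <- discarded
    return(rs)
  }
  bases <- paste0(tag, genomic[keep])

  if (error_rate > 0 && length(bases)) {
    chars <- strsplit(bases, "", fixed = TRUE)
    mat <- matrix(unlist(chars), nrow = read_length)
    hit <- matrix(runif(length(mat)) < error_rate, nrow = read_length)
    if (any(hit)) {
      # substitute with one of the three other bases, uniformly
      alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
      orig <- mat[hit]
      pick <- sample.int(3L, sum(hit), replace = TRUE)
      mat[hit] <- vapply(seq_along(orig),
                         function(i) alt[[orig[i]]][pick[i]], character(1))
    }
    bases <- apply(mat, 2, paste, collapse = "")
  }

  ids <- sprintf("read%07d %s:%d:%s", seq_along(bases),
                 replicon[keep], position[keep], strand[keep])
  rs <- read_set(ids, bases, rep(strrep("I", read_length), length(bases)),
                 tag = tag, error_rate = error_rate)
  attr(rs, "discarded_overrun") <- discarded
  rs
}

#' Write a read set as FASTQ (Sanger qualities)
#' @param reads a `read_set`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path.
#' @param tag the tag the reads are expected to start with (stored, not checked).
#' @return a `read_set`.
#' @export
read_fastq <- function(path, tag = "") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(names(x), as.character(x),
           as.character(S4Vectors::mcols(x)$qualities), tag = tag)
}
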