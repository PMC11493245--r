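#' Construct an insertion library
#'
#' An insertion library is a table of transposon insertion records:
#' one row per distinct (replicon, position, strand) site with the number of
#' mutants carrying that exact insertion. Positions are 0-based offsets of the
#' transposon-genome junction.
#'
#' @param replicon,position,strand,abundance vectors of equal length.
#' @param label library state, `"input"` or `"output"`.
#' @param ref optional `ref_assembly` used to bound-check positions.
#' @return a data.frame of class `insertion_library` with attribute `label`.
#' @export
insertion_library <- function(replicon, position, strand, abundance,
                              label = c("input", "output"), ref = NULL) {
  label <- match.arg(label)
  df <- data.frame(replicon = as.character(replicon),
                   position = as.integer(position),
                   strand = as.character(strand),
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
  if (any(df$abundance < 0)) stop("abundances must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(ref)) {
    lens <- replicon_lengths(ref)
    if (!all(df$replicon %in% names(lens)))
      stop("library refers to unknown replicon(s)")
    if (any(df$position < 0) || any(df$position >= lens[df$replicon]))
      stop("insertion positions out of replicon bounds")
  }
  # collapse duplicate site keys, summing mutant counts
  key <- paste(df$replicon, df$position, df$strand, sep = "\r")
  if (anyDuplicated(key)) {
    ab <- tapply(df$abundance, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$abundance <- as.numeric(ab[paste(df$replicon, df$position, df$strand,
                                        sep = "\r")])
  }
  df <- df[order(df$replicon, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("insertion_library", "data.frame"))
}

#' Library state label ("input" or "output")
#' @param lib an `insertion_library`.
#' @return character scalar.
#' @export
library_label <- function(lib) attr(lib, "label")

#' Simulate a dense Tn5 insertion library
#'
#' Draws `n_mutants` independent insertions uniformly over every position of
#' every replicon (so larger replicons receive proportionally more mutants),
#' with a uniform random strand per insertion. Each mutant carries exactly one
#' insertion; mutants hitting the same site and strand are summed into one
#' record. The Tn5 9-bp target-site duplication is ignored: an insertion is a
#' point junction position.
#'
#' @param ref a `ref_assembly`.
#' @param n_mutants number of mutants to draw (>= 0).
#' @param seed integer seed.
#' @return an `insertion_library` labelled `"input"`.
#' @export
simulate_insertion_library <- function(ref, n_mutants, seed = 1L) {
  if (length(ref$seqs) == 0) stop("empty reference")
  if (n_mutants < 0) stop("n_mutants must be >= 0")
  set.seed(seed)
  lens <- replicon_lengths(ref)
  if (n_mutants == 0)
    return(insertion_library(character(0), integer(0), character(0),
                             numeric(0), label = "input"))
  offset <- sample.int(sum(lens), n_mutants, replace = TRUE) - 1L
  cum <- cumsum(as.numeric(lens))
  idx <- findInterval(offset, cum) + 1L
  position <- offset - c(0, cum)[idx]
  strand <- sample(c("+", "-"), n_mutants, replace = TRUE)
  insertion_library(names(lens)[idx], position, strand,
                    rep(1, n_mutants), label = "input", ref = ref)
}

#' Define a conjugation selection model
#'
#' A mutant in the recipient library acquires the mobilized plasmid with
#' probability `base_rate`, multiplied by a per-gene effect `epsilon` when the
#' mutant's insertion disrupts that gene (epsilon > 1 for exclusion genes
#' whose disruption enhances acquisition) or by `intergenic` otherwise.
#' Probabilities are clamped to 1 at sampling time.
#'
#' @param base_rate acquisition probability in \[0, 1\] for an unaffected mutant.
#' @param effects named numeric vector, gene_id -> multiplier (>= 0).
#' @param intergenic multiplier for insertions outside any gene.
#' @return an object of class `selection_model`.
#' @export
selection_model <- function(base_rate, effects = numeric(0), intergenic = 1) {
  if (base_rate < 0 || base_rate > 1) stop("base_rate must be in [0, 1]")
  if (length(effects) && (is.null(names(effects)) || any(effects < 0)))
    stop("effects must be a named vector of non-negative multipliers")
  if (intergenic < 0) stop("intergenic multiplier must be >= 0")
  structure(list(base_rate = base_rate, effects = effects,
                 intergenic = intergenic), class = "selection_model")
}

# gene containing each site, NA_character_ for intergenic; start <= pos < end
locate_in_genes <- function(replicon, position, annotation) {
  out <- rep(NA_character_, length(position))
  for (i in seq_len(nrow(annotation))) {
    hit <- replicon == annotation$replicon[i] &
      position >= annotation$start[i] & position < annotation$end[i]
    out[hit] <- annotation$gene_id[i]
  }
  out
}

#' Apply conjugation selection to an input library
#'
#' Each mutant is retained independently with probability
#' `min(1, base_rate * epsilon)`, where `epsilon` is the effect multiplier of
#' the gene containing its insertion (or the intergenic multiplier). Sites are
#' thinned binomially, so the output site set is always a subset of the input.
#'
#' @param lib an `insertion_library` labelled `"input"`.
#' @param model a `selection_model`.
#' @param annotation gene annotation data.frame.
#' @param seed integer seed.
#' @return an `insertion_library` labelled `"output"`.
#' @export
apply_conjugation_selection <- function(lib, model, annotation, seed = 1L) {
  stopifnot(inherits(lib, "insertion_library"), inherits(model, "selection_model"))
  if (library_label(lib) != "input") stop("selection applies to an input library")
  validate_annotation(annotation)
  set.seed(seed)
  gene <- locate_in_genes(lib$replicon, lib$position, annotation)
  mult <- rep(model$intergenic, nrow(lib))
  hit <- !is.na(gene) & gene %in% names(model$effects)
  mult[hit] <- model$effects[gene[hit]]
  p <- pmin(1, model$base_rate * mult)
  kept <- rbinom(nrow(lib), size = as.integer(lib$abundance), prob = p)
  keep <- kept > 0
  insertion_library(lib$replicon[keep], lib$position[keep], lib$strand[keep],
                    kept[keep], label = "output")
}

#' Write an insertion library as TSV
#'
#' Columns: replicon, position, strand, abundance; the library label is kept
#' in a `# label=` header comment.
#'
#' @param lib an `insertion_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s", library_label(lib)), con)
  write.table(as.data.frame(lib), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an insertion library from TSV
#' @param path path written by [write_library_tsv()].
#' @return an `insertion_library`.
#' @export
read_library_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  label <- sub("^# label=", "", first)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  insertion_library(df$replicon, df$position, df$strand, df$abundance,
                    label = label)
}
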