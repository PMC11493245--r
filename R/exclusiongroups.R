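#' Assemble an sfx x traN exclusion-index matrix
#'
#' For each traN variant (donor side), the exclusion index toward each sfx
#' variant (recipient side) is the transfer frequency into the empty recipient
#' divided by the frequency into the recipient expressing that sfx variant.
#' Frequencies are summarized per (traN, sfx) cell by the geometric mean over
#' replicates (per-replicate EIs are available via `per_replicate = TRUE`,
#' which returns the long table instead of the matrix). Censored test
#' frequencies (no transconjugants) propagate as lower-bound flags.
#'
#' @param matings mating-record data.frame with `sfx_variant` and
#'   `traN_variant` metadata columns (see [read_mating_csv()]).
#' @param reference_recipient the `sfx_variant` label of the empty recipient
#'   used as the EI numerator (default `"empty"`).
#' @param per_replicate return per-replicate EIs as a long data.frame.
#' @return an object of class `exclusion_matrix`: a numeric matrix of EIs
#'   (rows = sfx variants, columns = traN variants) with a logical
#'   `lower_bound` matrix attribute; or a long data.frame if
#'   `per_replicate = TRUE`.
#' @export
build_exclusion_matrix <- function(matings, reference_recipient = "empty",
                                   per_replicate = FALSE) {
  if (!all(c("sfx_variant", "traN_variant") %in% names(matings)))
    stop("matings must carry sfx_variant and traN_variant columns")
  matings <- mating_frequencies(matings)
  tra <- unique(matings$traN_variant)
  sfx <- setdiff(unique(matings$sfx_variant), reference_recipient)
  miss <- tra[!vapply(tra, function(t)
    any(matings$traN_variant == t &
          matings$sfx_variant == reference_recipient), logical(1))]
  if (length(miss))
    stop("no empty-recipient baseline mating for traN column(s): ",
         paste(miss, collapse = ", "))
  if (per_replicate) {
    rows <- list()
    for (t in tra) {
      base <- matings[matings$traN_variant == t &
                        matings$sfx_variant == reference_recipient, ]
      t_empty <- geometric_mean(base$frequency)
      for (s in sfx) {
        test <- matings[matings$traN_variant == t & matings$sfx_variant == s, ]
        if (nrow(test) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          sfx_variant = s, traN_variant = t, replicate = test$replicate,
          EI = t_empty / test$frequency, lower_bound = test$censored)
      }
    }
    return(do.call(rbind, rows))
  }
  ei <- matrix(NA_real_, length(sfx), length(tra), dimnames = list(sfx, tra))
  lb <- matrix(FALSE, length(sfx), length(tra), dimnames = list(sfx, tra))
  for (t in tra) {
    base <- matings[matings$traN_variant == t &
                      matings$sfx_variant == reference_recipient, ]
    t_empty <- geometric_mean(base$frequency)
    for (s in sfx) {
      test <- matings[matings$traN_variant == t & matings$sfx_variant == s, ]
      if (nrow(test) == 0) next
      ei[s, t] <- t_empty / geometric_mean(test$frequency)
      lb[s, t] <- all(test$censored)
    }
  }
  structure(ei, lower_bound = lb, class = c("exclusion_matrix", "matrix"))
}

#' Infer surface exclusion groups from an exclusion-index matrix
#'
#' Cells are binarized at the cutoff (excluded iff EI >= cutoff; lower-bound
#' cells count as excluded when their bound reaches the cutoff). traN variants
#' with identical binary exclusion profiles across all sfx variants form one
#' exclusion group; each sfx variant is assigned the set of groups it
#' excludes. Missing cells are treated as EI = 1 (no exclusion) with a
#' warning.
#'
#' @param mat an `exclusion_matrix` (or plain numeric matrix, rows = sfx,
#'   columns = traN).
#' @param exclusion_threshold EI cutoff separating exclusion from its absence
#'   (default 10, one order of magnitude).
#' @return an object of class `exclusion_partition`: list with `groups`
#'   (named list of traN label vectors), `sfx_assignment` (named list: sfx ->
#'   group names it excludes) and the `binary` matrix.
#' @export
infer_exclusion_groups <- function(mat, exclusion_threshold = 10) {
  m <- unclass(mat)
  if (anyNA(m)) {
    warning("missing exclusion-index cells treated as EI = 1")
    m[is.na(m)] <- 1
  }
  binary <- m >= exclusion_threshold
  profile <- apply(binary, 2, paste, collapse = "/")
  uniq <- unique(profile)
  groups <- lapply(uniq, function(p) colnames(m)[profile == p])
  names(groups) <- paste0("group", seq_along(groups))
  sfx_assignment <- lapply(rownames(m), function(s) {
    names(groups)[vapply(groups, function(g) any(binary[s, g]), logical(1))]
  })
  names(sfx_assignment) <- rownames(m)
  structure(list(groups = groups, sfx_assignment = sfx_assignment,
                 binary = binary, threshold = exclusion_threshold),
            class = "exclusion_partition")
}

#' @export
print.exclusion_partition <- function(x, ...) {
  cat(sprintf("Exclusion groups (EI >= %g):\n", x$threshold))
  for (g in names(x$groups))
    cat(sprintf("  %s: %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  cat("sfx assignments:\n")
  for (s in names(x$sfx_assignment))
    cat(sprintf("  %s -> %s\n", s,
                if (length(x$sfx_assignment[[s]]))
                  paste(x$sfx_assignment[[s]], collapse = ", ") else "(none)"))
  invisible(x)
}

#' Simulate a mating CFU table with planted exclusion structure
#'
#' Generates replicated mating records for every (sfx recipient, traN donor)
#' combination plus the empty-recipient baselines. The transfer frequency
#' into the empty recipient is `base_frequency`; the frequency into a
#' recipient expressing an sfx variant is divided by the planted EI of that
#' cell. Log-normal replicate noise (`sdlog`, on the log10 scale) emulates
#' day-to-day variation of mating assays; CFU counts are rounded Poisson-free
#' deterministic products of frequency and donor count.
#'
#' @param planted_ei numeric matrix of planted exclusion indices, rows = sfx
#'   variants, columns = traN variants (dimnames required).
#' @param base_frequency transfer frequency toward the empty recipient.
#' @param donor_cfu donor CFU/ml per mating.
#' @param replicates replicates per combination.
#' @param sdlog replicate-to-replicate standard deviation of log10 frequency.
#' @param reference_recipient label for the empty recipient.
#' @param seed integer seed.
#' @return a mating-record data.frame suitable for
#'   [build_exclusion_matrix()].
#' @export
simulate_mating_table <- function(planted_ei, base_frequency = 1e-3,
                                  donor_cfu = 1e9, replicates = 3,
                                  sdlog = 0.1,
                                  reference_recipient = "empty", seed = 1L) {
  stopifnot(!is.null(rownames(planted_ei)), !is.null(colnames(planted_ei)))
  set.seed(seed)
  rows <- list()
  add <- function(sfx, tra, freq) {
    for (r in seq_len(replicates)) {
      f <- 10^(log10(freq) + rnorm(1, 0, sdlog))
      tc <- round(f * donor_cfu)
      rows[[length(rows) + 1L]] <<- data.frame(
        donor_label = paste0("donor_", tra),
        recipient_label = paste0("recipient_", sfx),
        sfx_variant = sfx, traN_variant = tra, replicate = r,
        donor_cfu = donor_cfu, recipient_cfu = donor_cfu,
        transconjugant_cfu = tc)
    }
  }
  for (tra in colnames(planted_ei)) {
    add(reference_recipient, tra, base_frequency)
    for (sfx in rownames(planted_ei))
      add(sfx, tra, base_frequency / planted_ei[sfx, tra])
  }
  do.call(rbind, rows)
}

#' Write an exclusion matrix and its partition to disk
#'
#' Writes the EI matrix as TSV, the binarized matrix as TSV, the partition as
#' JSON, and (optionally) a log10-EI heatmap as PDF.
#'
#' @param mat an `exclusion_matrix`.
#' @param partition an `exclusion_partition`.
#' @param prefix output path prefix; files `<prefix>_ei.tsv`,
#'   `<prefix>_binary.tsv`, `<prefix>_groups.json`, `<prefix>_heatmap.pdf`.
#' @param heatmap also render the heatmap (default TRUE).
#' @return character vector of written paths, invisibly.
#' @export
write_exclusion_outputs <- function(mat, partition, prefix, heatmap = TRUE) {
  paths <- character(0)
  p <- paste0(prefix, "_ei.tsv")
  write.table(as.data.frame(unclass(mat)), p, sep = "\t", quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_binary.tsv")
  write.table(as.data.frame(partition$binary), p, sep = "\t", quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_groups.json")
  jsonlite::write_json(list(threshold = partition$threshold,
                            groups = partition$groups,
                            sfx_assignment = partition$sfx_assignment),
                       p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  if (heatmap) {
    p <- paste0(prefix, "_heatmap.pdf")
    plot_exclusion_heatmap(mat, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Heatmap of log10 exclusion indices
#' @param mat an `exclusion_matrix`.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_exclusion_heatmap <- function(mat, path) {
  pdf(path, width = 6, height = 5)
  pheatmap::pheatmap(log10(unclass(mat)), cluster_rows = FALSE,
                     cluster_cols = FALSE,
                     main = "log10 exclusion index")
  dev.off()
  invisible(path)
}
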