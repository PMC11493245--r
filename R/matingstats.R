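#' Transfer frequency from CFU counts
#'
#' The transfer frequency of a mating is the number of transconjugant CFUs
#' divided by the number of donor CFUs. When no transconjugant colony was
#' observed the frequency is censored at the detection limit `1/donor_cfu`
#' (one colony on the plated volume), so log-scale analyses can retain the
#' replicate; the `censored` flag records this.
#'
#' @param donor_cfu donor CFU/ml counts (> 0), vectorized.
#' @param transconjugant_cfu transconjugant CFU/ml counts (>= 0).
#' @return a data.frame with columns `value` and `censored`.
#' @export
transfer_frequency <- function(donor_cfu, transconjugant_cfu) {
  if (any(donor_cfu <= 0)) stop("donor_cfu must be > 0")
  if (any(transconjugant_cfu < 0)) stop("transconjugant_cfu must be >= 0")
  censored <- transconjugant_cfu == 0
  value <- ifelse(censored, 1 / donor_cfu, transconjugant_cfu / donor_cfu)
  data.frame(value = value, censored = censored)
}

#' Exclusion index from two transfer frequencies
#'
#' EI is the element's transfer frequency toward an empty recipient divided by
#' its frequency toward the tested recipient; EI near 1 means no exclusion.
#' When the test frequency is censored at its detection limit the EI is a
#' lower bound, recorded in `lower_bound`.
#'
#' @param freq_empty,freq_test rows (or vectors recycled) as returned by
#'   [transfer_frequency()]: lists/data.frames with `value` and `censored`.
#' @return a data.frame with columns `value` and `lower_bound`.
#' @export
exclusion_index <- function(freq_empty, freq_test) {
  if (any(freq_empty$value <= 0)) stop("empty-recipient frequency must be > 0")
  if (any(freq_test$value <= 0)) stop("test frequency must be > 0 (censor zeros upstream)")
  data.frame(value = freq_empty$value / freq_test$value,
             lower_bound = as.logical(freq_test$censored))
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups)) stop("groups must be a list of numeric vectors")
  lapply(groups, as.numeric)
}

#' Bartlett's test of homogeneity of variances
#'
#' Thin wrapper over [stats::bartlett.test()] for lists of (typically log10-
#' transformed) transfer frequencies.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `statistic` (chi-squared), `df` and `p.value`.
#' @export
bartlett_test <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  bt <- bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p.value = bt$p.value)
}

# between/within sums of squares shared by the ANOVA and Tukey machinery
anova_decomposition <- function(groups) {
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  list(n = n, means = means, ssb = ssb, ssw = ssw,
       df1 = k - 1L, df2 = sum(n) - k,
       msb = ssb / (k - 1L), msw = ssw / (sum(n) - k))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance by the between/within
#' sums-of-squares decomposition, for (log10-transformed) transfer
#' frequencies. Degenerate inputs with zero within- and between-group
#' variance return F = 0, p = 1.
#'
#' @param groups list of numeric vectors.
#' @return list with `F`, `df1`, `df2`, `p.value`, and the underlying
#'   decomposition (`ssb`, `ssw`, `msw`, group `means`, `n`).
#' @export
anova_oneway <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need >= 2 groups")
  d <- anova_decomposition(groups)
  if (d$df2 <= 0) stop("total n must exceed the number of groups")
  if (d$msw == 0) {
    if (d$ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- d$msb / d$msw
    p <- pf(f, d$df1, d$df2, lower.tail = FALSE)
  }
  c(list(F = f, p.value = p), d)
}

#' Tukey-Kramer all-pairs comparisons
#'
#' For each pair of groups computes the studentized range statistic
#' `q = |m_i - m_j| / sqrt((MSW/2) (1/n_i + 1/n_j))` (the Kramer adjustment
#' handles unequal group sizes) and its p-value from the studentized range
#' distribution with `k` groups and the ANOVA within degrees of freedom.
#'
#' @param groups list of numeric vectors (named; names label the matrix).
#' @return symmetric matrix of adjusted pairwise p-values, diagonal 1.
#' @export
tukey_kramer <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- anova_decomposition(groups)
  if (d$df2 <= 0) stop("total n must exceed the number of groups")
  k <- length(groups)
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      diffm <- abs(d$means[i] - d$means[j])
      if (d$msw == 0) {
        pij <- if (diffm == 0) 1 else 0
      } else {
        q <- diffm / sqrt((d$msw / 2) * (1 / d$n[i] + 1 / d$n[j]))
        pij <- ptukey(q, nmeans = k, df = d$df2, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb lettering: starting from one letter covering all groups,
#' each significant pair (p < alpha) splits letters so that the final display
#' satisfies "two groups share at least one letter iff their pairwise p-value
#' is >= alpha". The letter set is correct for the sharing relation but not
#' guaranteed minimal.
#'
#' @param pmat symmetric matrix of pairwise p-values with dimnames.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  if (k == 0) return(character(0))
  if (is.null(rownames(pmat))) dimnames(pmat) <- list(paste0("g", 1:k),
                                                      paste0("g", 1:k))
  if (!isTRUE(all.equal(pmat, t(pmat)))) stop("p matrix must be symmetric")
  groups <- rownames(pmat)
  # letters as a list of membership sets; start with one letter for everyone
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (pmat[i, j] >= alpha) next
      # significant pair: split every letter containing both i and j
      newcols <- list()
      for (set in cols) {
        if (i %in% set && j %in% set) {
          newcols <- c(newcols, list(setdiff(set, i)), list(setdiff(set, j)))
        } else {
          newcols <- c(newcols, list(set))
        }
      }
      # absorb: drop letters whose membership is a subset of another's
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a != b && keep[b] &&
              all(newcols[[a]] %in% newcols[[b]]) &&
              !(all(newcols[[b]] %in% newcols[[a]]) && a < b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  lab <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(g) {
    paste(lab[which(vapply(cols, function(set) g %in% set, logical(1)))],
          collapse = "")
  }, character(1))
  setNames(out, groups)
}

#' Full statistical treatment of grouped transfer frequencies
#'
#' Applies the standard analysis of mating-assay frequencies: log10
#' transformation, Bartlett's homogeneity test, one-way ANOVA, Tukey-Kramer
#' all-pairs post test and a compact letter display.
#'
#' @param freq data.frame with columns `group` and `value` (frequencies on
#'   the natural scale) or a named list of frequency vectors.
#' @param alpha significance level for the letter display.
#' @param log10_transform apply log10 before the analysis (default TRUE).
#' @return an object of class `group_comparison`: list with `groups` (log10
#'   data), `means`, `bartlett`, `anova`, `tukey` (p matrix) and `cld`.
#' @export
compare_groups <- function(freq, alpha = 0.05, log10_transform = TRUE) {
  groups <- as_group_list(freq)
  if (log10_transform) groups <- lapply(groups, log10)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  av <- anova_oneway(groups)
  tk <- tukey_kramer(groups)
  structure(list(groups = groups,
                 means = vapply(groups, mean, numeric(1)),
                 bartlett = bartlett_test(groups),
                 anova = av, tukey = tk,
                 cld = compact_letter_display(tk, alpha),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p.value))
  cat(sprintf("Bartlett: chi-sq(%d) = %.4g, p = %.3g\n",
              x$bartlett$df, x$bartlett$statistic, x$bartlett$p.value))
  cat("Group means (log10) and letters:\n")
  print(data.frame(mean = round(x$means, 3), letters = x$cld))
  invisible(x)
}

#' Read a mating-record CSV
#'
#' Expected header: `donor_label, recipient_label, replicate, donor_cfu,
#' recipient_cfu, transconjugant_cfu` plus optional metadata columns (e.g.
#' `sfx_variant`, `traN_variant`).
#'
#' @param path CSV path.
#' @return data.frame of mating records.
#' @export
read_mating_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor_label", "recipient_label", "replicate",
            "donor_cfu", "recipient_cfu", "transconjugant_cfu")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mating CSV column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Append transfer frequencies to a mating table
#' @param matings mating-record data.frame (see [read_mating_csv()]).
#' @return the table with `frequency` and `censored` columns added.
#' @export
mating_frequencies <- function(matings) {
  tf <- transfer_frequency(matings$donor_cfu, matings$transconjugant_cfu)
  matings$frequency <- tf$value
  matings$censored <- tf$censored
  matings
}

geometric_mean <- function(x) exp(mean(log(x)))
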