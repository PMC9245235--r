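# IARF questionnaire scoring and ordinal rater agreement.
#
# The IARF is a 10-item pharmacotherapy-review assessment instrument
# (adapted from the Medication Appropriateness Index): each item is coded
# 1 (No), 2 (Yes, but acceptable), 3 (Yes) or 9 (I do not know), "No" being
# optimal on every item, so an optimal review sums to exactly 10.  Item 10
# is the overall classification (adequate / partially adequate /
# inadequate / unknown).  Agreement between pairs of reviewers over the
# three-level classification is measured with weighted Cohen's kappa.

IARF_CODES <- c(1L, 2L, 3L, 9L)
IARF_N_ITEMS <- 10L
KAPPA_CATEGORIES <- c(adequate = 1L, partially_adequate = 2L, inadequate = 3L)

#' Score an IARF questionnaire response
#'
#' The total is the sum of codes over items answered 1/2/3; code 9
#' ("I do not know") is excluded from the sum and counted separately so
#' incomplete assessments are visible, never silently optimal.  With no
#' unknowns the total lies in `[10, 30]`, and equals 10 iff every item is
#' "No".  Item 10 maps to the overall review classification.
#'
#' @param items integer vector of exactly 10 codes in `{1, 2, 3, 9}`.
#' @return an `iarf_score`: `total`, `n_unknown`, `classification`.
#' @examples
#' score_iarf(rep(1, 10))  # optimal review: total 10, adequate
#' @export
score_iarf <- function(items) {
  items <- as.integer(items)
  if (length(items) != IARF_N_ITEMS) {
    stop("IARF response must have exactly ", IARF_N_ITEMS, " items, got ",
         length(items), call. = FALSE)
  }
  if (!all(items %in% IARF_CODES)) {
    stop("invalid IARF code(s): ", paste(setdiff(items, IARF_CODES), collapse = ", "),
         " (allowed: 1, 2, 3, 9)", call. = FALSE)
  }
  answered <- items != 9L
  classification <- switch(as.character(items[IARF_N_ITEMS]),
                           "1" = "adequate", "2" = "partially_adequate",
                           "3" = "inadequate", "9" = "unknown")
  structure(list(total = sum(items[answered]),
                 n_unknown = sum(!answered),
                 classification = classification),
            class = "iarf_score")
}

#' @export
print.iarf_score <- function(x, ...) {
  cat(sprintf("IARF total %d (%d item(s) answered 'I do not know'), review %s\n",
              x$total, x$n_unknown, x$classification))
  if (x$n_unknown > 0L) {
    cat("  note: unknowns are excluded from the total; assessment is incomplete\n")
  }
  invisible(x)
}

# ---- weighted kappa ---------------------------------------------------------

kappa_weight_matrix <- function(scheme, k) {
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  switch(scheme,
         linear = abs(i - j) / (k - 1),
         quadratic = ((i - j) / (k - 1))^2,
         identity = (i != j) * 1,
         stop("unknown weight scheme '", scheme, "' (linear, quadratic, identity)",
              call. = FALSE))
}

rating_table <- function(a, b, k = 3L) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("rating vectors must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 rated units", call. = FALSE)
  if (!all(c(a, b) %in% seq_len(k))) {
    stop("ratings must be integers in 1..", k, call. = FALSE)
  }
  table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
}

#' Weighted Cohen's kappa for paired ordinal ratings
#'
#' \eqn{\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}} with
#' disagreement weights \eqn{w_{ij}} (linear: \eqn{|i-j|/(k-1)};
#' quadratic: \eqn{((i-j)/(k-1))^2}; identity: \eqn{1_{i \ne j}}, which
#' reduces to unweighted Cohen's kappa), observed cell proportions
#' \eqn{O} and chance-expected proportions \eqn{E} from the marginals.
#' The weight scheme is a mandatory explicit argument.
#'
#' @param a,b integer rating vectors over the ordered categories `1..k`
#'   (default 3: adequate / partially adequate / inadequate).
#' @param weights `"linear"`, `"quadratic"` or `"identity"`.
#' @param k number of ordered categories.
#' @return kappa value in `[-1, 1]`.
#' @examples
#' weighted_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2), weights = "identity", k = 2)  # 0
#' @export
weighted_kappa <- function(a, b, weights, k = 3L) {
  tab <- rating_table(a, b, k)
  w <- kappa_weight_matrix(weights, k)
  n <- sum(tab)
  O <- tab / n
  E <- outer(rowSums(O), colSums(O))
  de <- sum(w * E)
  if (de == 0) {
    stop("degenerate marginals: expected disagreement is zero, kappa undefined",
         call. = FALSE)
  }
  1 - sum(w * O) / de
}

# Non-null asymptotic variance of weighted kappa (Fleiss, Cohen & Everitt
# 1969), on agreement weights v = 1 - w.
weighted_kappa_var <- function(tab, w) {
  n <- sum(tab)
  O <- tab / n
  pr <- rowSums(O)
  pc <- colSums(O)
  v <- 1 - w
  po <- sum(v * O)
  pe <- sum(v * outer(pr, pc))
  kap <- (po - pe) / (1 - pe)
  vi <- drop(v %*% pc)   # row agreement means under the column marginals
  vj <- drop(pr %*% v)   # column agreement means under the row marginals
  term <- outer(vi, vj, function(x, y) x + y) * (1 - kap)
  s <- sum(O * (v - term)^2)
  num <- s - (kap - pe * (1 - kap))^2
  num / (n * (1 - pe)^2)
}

#' Confidence interval for weighted kappa
#'
#' Asymptotic interval from the large-sample (non-null) variance of
#' Fleiss, Cohen & Everitt (1969), clipped to `[-1, 1]`; a nonparametric
#' bootstrap over rated units is offered because agreement studies are
#' often small.  The method used is recorded in the result.
#'
#' @inheritParams weighted_kappa
#' @param level confidence level (default 0.95).
#' @param method `"asymptotic"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list `kappa`, `lower`, `upper`, `level`, `method`.
#' @export
kappa_ci <- function(a, b, weights, level = 0.95, k = 3L,
                     method = c("asymptotic", "bootstrap"),
                     n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  kap <- weighted_kappa(a, b, weights, k)
  if (method == "asymptotic") {
    tab <- rating_table(a, b, k)
    v <- weighted_kappa_var(tab, kappa_weight_matrix(weights, k))
    se <- sqrt(max(v, 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(-1, kap - z * se)
    hi <- min(1, kap + z * se)
  } else {
    n <- length(a)
    reps <- run_seeded(seed, {
      vapply(seq_len(n_boot), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(weighted_kappa(a[idx], b[idx], weights, k), error = function(e) NA_real_)
      }, 0)
    })
    reps <- reps[!is.na(reps)]
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- max(-1, qs[1L])
    hi <- min(1, qs[2L])
  }
  list(kappa = kap, lower = lo, upper = hi, level = level, method = method)
}

#' Interpret a kappa value on the standard agreement bands
#'
#' Bands (closed intervals on the value rounded to 2 decimals): below 0
#' "poor", 0.00–0.20 "slight", 0.21–0.40 "reasonable", 0.41–0.60
#' "moderate", 0.61–0.80 "substantial", 0.81–1.00 "almost_perfect".
#'
#' @param value kappa in `[-1, 1]`.
#' @return band label.
#' @examples
#' interpret_kappa(0.3547)  # "reasonable"
#' interpret_kappa(0.4790)  # "moderate"
#' @export
interpret_kappa <- function(value) {
  if (is.na(value) || value < -1 || value > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  v <- round(value, 2)
  if (v < 0) "poor"
  else if (v <= 0.20) "slight"
  else if (v <= 0.40) "reasonable"
  else if (v <= 0.60) "moderate"
  else if (v <= 0.80) "substantial"
  else "almost_perfect"
}
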