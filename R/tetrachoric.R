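# Tetrachoric correlation of binary endorsements.
#
# Two-step estimator: thresholds from the marginal normal quantiles of the
# (continuity-corrected) 2x2 table, then the latent correlation by
# maximizing the bivariate-normal multinomial likelihood over rho. This is
# the standard practice of psychometric implementations and is far more
# stable than joint trivariate ML when evaluated over tens of thousands of
# pairs.

#' Tetrachoric correlation from a 2x2 table
#'
#' Cells follow the convention `a` = both endorsed, `b` = first only,
#' `c` = second only, `d` = neither. A 0.5 continuity correction is applied
#' to any zero cell. A table whose *raw* row or column margin is zero has
#' no information about the correlation and returns `NA` with
#' `defined = FALSE`.
#'
#' @param a,b,c,d non-negative cell counts, `a + b + c + d >= 2`.
#' @return list: `rho`, `tau_x`, `tau_y` (latent thresholds), `defined`,
#'   `n` (raw total).
#' @export
tetrachoric <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_raw <- a + b + c + d
  if (n_raw < 2) stop("tetrachoric needs a table total of at least 2",
                      call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(rho = NA_real_, tau_x = NA_real_, tau_y = NA_real_,
                defined = FALSE, n = n_raw))
  }
  cells <- c(a, b, c, d)
  cells[cells == 0] <- 0.5
  n <- sum(cells)
  px <- (cells[1] + cells[2]) / n        # P(first = 1)
  py <- (cells[1] + cells[3]) / n
  tau_x <- stats::qnorm(1 - px)
  tau_y <- stats::qnorm(1 - py)
  nll <- function(rho) {
    p11 <- pbvnorm(-tau_x, -tau_y, rho)
    p10 <- (1 - stats::pnorm(tau_x)) - p11
    p01 <- (1 - stats::pnorm(tau_y)) - p11
    p00 <- 1 - p11 - p10 - p01
    p <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(cells * log(p))
  }
  opt <- stats::optimize(nll, c(-0.9999, 0.9999), tol = 1e-9)
  list(rho = opt$minimum, tau_x = tau_x, tau_y = tau_y,
       defined = TRUE, n = n_raw)
}

#' Pairwise tetrachoric matrix over medication x side-effect columns
#'
#' One column per (medication, checklist side effect) endorsement; each
#' pair is evaluated on the pairwise-complete participants (those exposed
#' to both medications). Pairs with fewer than `min_pair_n` complete
#' observations or a degenerate margin are flagged undefined (`NA`).
#'
#' @param cohort a `cohort_table`.
#' @param medications drugs to include (default all 10).
#' @param side_effects effects to include (default the 23 checklist items).
#' @param min_pair_n minimum pairwise-complete sample size (default 30).
#' @return object of class `tetra_matrix`: `labels` (data.frame medication,
#'   side_effect), `rho`, `n_pair` (symmetric matrices) and `undefined`
#'   (logical matrix).
#' @export
tetra_matrix <- function(cohort, medications = .DRUGS,
                         side_effects = .CHECKLIST, min_pair_n = 30L) {
  cols <- expand.grid(side_effect = side_effects, medication = medications,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  cn <- paste0("se_", cols$medication, "_", cols$side_effect)
  Y <- as.matrix(cohort[, cn, drop = FALSE])
  p <- ncol(Y)
  A1 <- (!is.na(Y)) & Y == 1L   # endorsed
  A0 <- (!is.na(Y)) & Y == 0L   # exposed, not endorsed
  storage.mode(A1) <- "numeric"
  storage.mode(A0) <- "numeric"
  n11 <- crossprod(A1)          # both endorsed
  n10 <- crossprod(A1, A0)      # row var endorsed, col var not
  n00 <- crossprod(A0)
  rho <- matrix(NA_real_, p, p)
  npair <- matrix(0L, p, p)
  diag(rho) <- 1
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      a <- n11[i, j]; b <- n10[i, j]; cc <- n10[j, i]; d <- n00[i, j]
      tot <- a + b + cc + d
      npair[i, j] <- npair[j, i] <- tot
      if (tot < max(2L, min_pair_n)) next
      tc <- tetrachoric(a, b, cc, d)
      if (tc$defined) rho[i, j] <- rho[j, i] <- tc$rho
    }
  }
  npair[cbind(seq_len(p), seq_len(p))] <- colSums(A1 + A0)
  dimnames(rho) <- dimnames(npair) <- list(cn, cn)
  structure(list(labels = cols, rho = rho, n_pair = npair,
                 undefined = is.na(rho) &
                   row(rho) != col(rho)),
            class = "tetra_matrix")
}

#' @export
print.tetra_matrix <- function(x, ...) {
  p <- nrow(x$rho)
  cat("<tetra_matrix> ", p, " columns, ",
      sum(x$undefined[upper.tri(x$undefined)]), " undefined pair(s)\n",
      sep = "")
  invisible(x)
}

#' Transform a correlation matrix to a distance matrix
#'
#' Uses `d = 1 - rho`. Undefined cells are imputed to the median of the
#' defined off-diagonal distances; the imputed count is recorded in the
#' `"n_imputed"` attribute and logged.
#'
#' @param m a `tetra_matrix` (or plain correlation matrix).
#' @return symmetric distance matrix with zero diagonal.
#' @export
corr_to_dist <- function(m) {
  rho <- if (inherits(m, "tetra_matrix")) m$rho else m
  d <- 1 - rho
  diag(d) <- 0
  off <- d[row(d) != col(d)]
  n_missing <- sum(is.na(off)) / 2
  if (n_missing > 0) {
    med <- stats::median(off, na.rm = TRUE)
    if (is.na(med)) med <- 1   # every pair undefined: neutral distance
    d[is.na(d)] <- med
    sidefx_log("corr_to_dist: imputed ", n_missing,
               " undefined pair distance(s) to the median ", round(med, 4))
  }
  attr(d, "n_imputed") <- n_missing
  d
}

#' Median co-occurrence summaries
#'
#' Median tetrachoric correlation among pairs that share the side effect
#' (different medications), pairs that share the medication (different side
#' effects), and pairs sharing neither — the three-way decomposition used
#' to argue that side effects track people rather than medications.
#'
#' @param m a `tetra_matrix`.
#' @return list with `within_side_effect`, `within_medication`, `across`
#'   medians and the pair counts behind each; empty categories are `NA`
#'   with a zero count.
#' @export
summarize_cooccurrence <- function(m) {
  stopifnot(inherits(m, "tetra_matrix"))
  p <- nrow(m$rho)
  med <- m$labels$medication
  eff <- m$labels$side_effect
  ut <- which(upper.tri(m$rho), arr.ind = TRUE)
  same_eff <- eff[ut[, 1]] == eff[ut[, 2]]
  same_med <- med[ut[, 1]] == med[ut[, 2]]
  vals <- m$rho[ut]
  catmed <- function(keep) {
    v <- vals[keep & !is.na(vals)]
    list(median = if (length(v) == 0L) NA_real_ else stats::median(v),
         n_pairs = length(v))
  }
  list(within_side_effect = catmed(same_eff & !same_med),
       within_medication = catmed(same_med & !same_eff),
       across = catmed(!same_med & !same_eff))
}
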