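#' Paired-samples t test
#'
#' Classical paired t statistic on `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the `n - 1` denominator sample
#' standard deviation, `df = n - 1`, and a two-sided Student-t p value.
#' When every difference is exactly zero the statistic is defined as
#' `t = 0`, `p = 1`; a zero standard deviation with a non-zero mean is
#' degenerate and raises an error.
#'
#' @param x,y equal-length numeric vectors (`n >= 2`).
#' @return list with `t`, `df` and `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("paired t test needs n >= 2")
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    stop("degenerate paired t test: zero variance with non-zero mean")
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1L, p = 2 * pt(-abs(tt), df = n - 1L))
}

#' Bonferroni significance decisions
#'
#' Significant iff `p < alpha / m` (strict inequality; for the default
#' three long-axis comparisons the threshold is 0.05/3).
#'
#' @param p numeric p values in `[0, 1]`.
#' @param m number of comparisons (>= 1), default 3.
#' @param alpha family-wise level, default 0.05.
#' @return logical vector.
#' @export
bonferroni_decisions <- function(p, m = 3, alpha = 0.05) {
  stopifnot(m >= 1)
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p < alpha / m
}

axis_patterns <- c("gradient_ap", "posterior_bias", "anterior_bias",
                   "body_bias", "other")

#' Classify a long-axis connectivity pattern
#'
#' Deterministic rule table over the head/body/tail means and the three
#' paired-comparison significance decisions (head-body, body-tail,
#' head-tail), evaluated in precedence order:
#' \describe{
#'   \item{gradient_ap}{all three significant and increasing means
#'     head < body < tail (anterior-to-posterior gradient).}
#'   \item{anterior_bias}{head-body not significant, the other two
#'     significant, tail lowest (preferential anterior 2/3).}
#'   \item{posterior_bias}{head-body and head-tail significant,
#'     body-tail not, head lowest (preferential posterior 2/3).}
#'   \item{body_bias}{head-body significant and body the largest mean.}
#'   \item{other}{anything else.}
#' }
#'
#' @param means numeric `c(head, body, tail)` means.
#' @param decisions logical `c(head_body, body_tail, head_tail)`
#'   significance decisions.
#' @return one of `"gradient_ap"`, `"posterior_bias"`, `"anterior_bias"`,
#'   `"body_bias"`, `"other"`.
#' @export
classify_pattern <- function(means, decisions) {
  stopifnot(length(means) == 3L, all(is.finite(means)),
            length(decisions) == 3L)
  m_h <- means[1]; m_b <- means[2]; m_t <- means[3]
  s_hb <- isTRUE(decisions[1]); s_bt <- isTRUE(decisions[2])
  s_ht <- isTRUE(decisions[3])
  if (s_hb && s_bt && s_ht && m_h < m_b && m_b < m_t) return("gradient_ap")
  if (!s_hb && s_bt && s_ht && m_t < min(m_h, m_b)) return("anterior_bias")
  if (s_hb && !s_bt && s_ht && m_h < min(m_b, m_t)) return("posterior_bias")
  if (s_hb && m_b > m_h && m_b > m_t) return("body_bias")
  "other"
}

#' Per-parcel long-axis statistics across subjects
#'
#' For each parcel, computes head/body/tail means and standard errors
#' across subjects, the three Bonferroni-corrected paired t tests
#' (head-body, body-tail, head-tail), and the long-axis pattern from
#' [classify_pattern()].
#'
#' @param tables list of `connectivity_table` objects (one per subject)
#'   with matching parcel names.
#' @param alpha family-wise level, default 0.05.
#' @param m number of comparisons for the Bonferroni correction,
#'   default 3.
#' @return data frame with one row per parcel: means, SEMs, t/df/p per
#'   comparison, decisions and `pattern`.
#' @export
axis_stats <- function(tables, alpha = 0.05, m = 3) {
  stopifnot(length(tables) >= 2L)
  nm <- tables[[1]]$name
  for (tb in tables)
    if (!identical(tb$name, nm)) stop("tables have mismatched parcels")
  get <- function(col) sapply(tables, `[[`, col) # parcel x subject
  H <- get("head"); B <- get("body"); Tl <- get("tail")
  if (is.null(dim(H))) { H <- rbind(H); B <- rbind(B); Tl <- rbind(Tl) }
  n <- ncol(H)
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(seq_along(nm), function(i) {
    t_hb <- paired_t_test(H[i, ], B[i, ])
    t_bt <- paired_t_test(B[i, ], Tl[i, ])
    t_ht <- paired_t_test(H[i, ], Tl[i, ])
    p3 <- c(t_hb$p, t_bt$p, t_ht$p)
    dec <- bonferroni_decisions(p3, m = m, alpha = alpha)
    mh <- mean(H[i, ]); mb <- mean(B[i, ]); mt <- mean(Tl[i, ])
    data.frame(name = nm[i], mean_head = mh, mean_body = mb, mean_tail = mt,
               sem_head = sem(H[i, ]), sem_body = sem(B[i, ]),
               sem_tail = sem(Tl[i, ]),
               t_head_body = t_hb$t, p_head_body = t_hb$p,
               t_body_tail = t_bt$t, p_body_tail = t_bt$p,
               t_head_tail = t_ht$t, p_head_tail = t_ht$p,
               df = n - 1L,
               sig_head_body = dec[1], sig_body_tail = dec[2],
               sig_head_tail = dec[3],
               pattern = classify_pattern(c(mh, mb, mt), dec),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
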