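#' ANCOVA-style trend test of the stress effect on CV-squared
#'
#' Stacks per-gene observations from a stressed and a control clutch and
#' fits, by ordinary least squares, the model
#' `response ~ intercept + condition + log10(mean TPM + 1)`:
#' the condition coefficient estimates the shift in heterogeneity under
#' maternal stress after adjusting for expression level, the standard
#' confound of CV^2 comparisons (low-expression genes have inflated CV^2
#' through sampling noise alone). The fit is computed from the QR
#' decomposition of the design matrix; genes must be defined (positive
#' mean and CV^2) in both tables to contribute.
#'
#' @param momH,momC Moment tables from [clutch_moments()] on a shared gene
#'   universe.
#' @param response `"cv2"` (default) or `"log10cv2"`.
#' @param pseudocount Offset inside `log10(mean + pseudocount)`; default 1.
#' @return List of class `trend_fit`: `coefficients` data.frame (term,
#'   estimate, se, t, p), `df` residual degrees of freedom, `n`
#'   observations, `response`, and `residuals`/`design` for diagnostics.
#' @export
ancova_stress_trend <- function(momH, momC, response = c("cv2", "log10cv2"),
                                pseudocount = 1) {
  response <- match.arg(response)
  if (!setequal(momH$gene_id, momC$gene_id)) {
    stop("moment tables do not share a gene universe", call. = FALSE)
  }
  momC <- momC[match(momH$gene_id, momC$gene_id), ]
  ok <- !is.na(momH$cv2) & !is.na(momC$cv2) & momH$cv2 > 0 & momC$cv2 > 0
  if (sum(ok) < 10) {
    stop("need at least 10 genes defined in both clutches", call. = FALSE)
  }
  cv2 <- c(momC$cv2[ok], momH$cv2[ok])
  y <- if (response == "cv2") cv2 else log10(cv2)
  cond <- rep(c(0, 1), each = sum(ok))
  logmean <- log10(c(momC$mean[ok], momH$mean[ok]) + pseudocount)
  X <- cbind(intercept = 1, condition = cond, log10_mean = logmean)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - as.vector(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = se, t = unname(tval), p = unname(pval),
                              row.names = NULL, stringsAsFactors = FALSE),
    df = df, n = length(y), response = response,
    pseudocount = pseudocount, residuals = res, design = X
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("ANCOVA-style trend fit (response: %s, n = %d, df = %d)\n",
              x$response, x$n, x$df))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact two-sided p-value by enumeration of all tables with the observed
#' margins: the hypergeometric probabilities of tables no more likely than
#' the observed one (up to a relative tolerance of 1e-7 for ties) are
#' summed. The alternative "doubling" convention — twice the smaller tail,
#' capped at 1 — is available via `rule`. A table with a zero margin
#' carries no information about association; its p-value is 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts (e.g. normal /
#'   abnormal development by maternal condition).
#' @param rule `"minlike"` (default, sum of probabilities at most the
#'   observed) or `"doubling"`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab, rule = c("minlike", "doubling")) {
  rule <- match.arg(rule)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)) ||
      any(!is.finite(tab))) {
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) stop("empty table", call. = FALSE)
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) {
    message("degenerate table (zero margin); p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  if (rule == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- 2 * min(lower, upper)
  }
  min(1, p)
}
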