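#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, at fixed margins, the hypergeometric
#' probabilities of all tables no more probable than the observed one. The
#' reported odds ratio is the sample cross-product `(a*d)/(b*c)` (not the
#' conditional MLE), with a 0.5 continuity correction applied to all cells
#' when any cell is zero — the convention used for reporting enrichment
#' odds ratios.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts; rows are groups, columns outcomes.
#' @return List: `odds_ratio`, `p_value`, `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative counts")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("counts must be integers")
  tab <- round(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) stop("empty table")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  if (lo > hi || m == 0 || n == 0 || k == 0 || b + d == 0) {
    p <- 1
  } else {
    probs <- stats::dhyper(lo:hi, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  if (any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * c), p_value = p, table = tab)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact by full enumeration of group assignments when the
#' combined sample size is at most `exact_below_n` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The statistic is the rank sum of `x`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_below_n Combined-size cutoff for exact enumeration
#'   (default 12).
#' @return List: `statistic` (rank sum of `x`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below_n = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  v <- c(x, y)
  r <- rank(v)
  W <- sum(r[seq_len(n1)])
  ties <- any(duplicated(v))
  if (n <= exact_below_n && !ties) {
    sums <- utils::combn(n, n1, function(idx) sum(r[idx]))
    mu <- n1 * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = W, p_value = p, exact = TRUE))
  }
  mu <- n1 * (n + 1) / 2
  tie_tab <- table(v)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p_value = 1, exact = FALSE))
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(statistic = W, p_value = min(1, 2 * stats::pnorm(-z)), exact = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with monotonicity enforced from the
#' largest p downwards; output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  q
}

#' Stepwise-AIC generalised linear model for kataegis presence or burden
#'
#' Fits a logistic model (binary presence) or a negative-binomial model
#' (event counts; dispersion estimated by maximum likelihood via
#' `MASS::glm.nb`) and selects covariates by bidirectional stepwise search
#' minimizing AIC, starting from the full model. Pre-processing mirrors
#' cohort practice: rows with missing values in the response or any
#' candidate covariate are dropped (and counted); when two candidate
#' covariates correlate beyond `cor_cutoff` in absolute value the
#' later-listed one is excluded before fitting; covariates named in
#' `log_covariates` are log1p-transformed (recommended for skewed counts
#' such as SV burden and CNV-loss bp under the negative-binomial model;
#' the logistic model makes no distributional assumption on covariates so
#' none are transformed by default).
#'
#' Complete separation in the logistic model (fitted probabilities pinned
#' at 0/1) is flagged; coefficients are still returned but their Wald
#' p-values are unreliable.
#'
#' @param data `data.frame` with the response and covariates.
#' @param response Response column name.
#' @param family `"logistic"` or `"negative_binomial"`.
#' @param covariates Character vector of candidate covariate names.
#' @param log_covariates Covariates to log1p-transform (default none).
#' @param cor_cutoff Absolute pairwise-correlation exclusion cutoff
#'   (default 0.6).
#' @return List of class `"kataegis_glm"`: `model`, `coefficients`
#'   (`data.table` with estimate, ratio = exp(estimate), se, p),
#'   `selected` (covariate names in the final model), `aic`, `trace`
#'   (captured stepwise log), `n_dropped_rows`, `excluded_covariates`,
#'   `separation`.
#' @export
stepwise_glm <- function(data, response, family = c("logistic", "negative_binomial"),
                         covariates, log_covariates = character(0),
                         cor_cutoff = 0.6) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  miss <- setdiff(c(response, covariates), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  cc <- stats::complete.cases(data[, c(response, covariates), drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  for (v in intersect(log_covariates, covariates)) {
    if (!is.numeric(data[[v]])) stop("cannot log-transform non-numeric ", v)
    if (any(data[[v]] < 0)) stop("negative values in log covariate ", v)
    data[[v]] <- log1p(data[[v]])
  }

  # pairwise-correlation exclusion among numeric candidates (keep earlier)
  excluded <- character(0)
  num <- covariates[vapply(covariates, function(v) is.numeric(data[[v]]), logical(1))]
  if (length(num) >= 2L) {
    cm <- abs(stats::cor(data[, num, drop = FALSE]))
    for (i in seq_along(num)) for (j in seq_along(num)) {
      if (j > i && isTRUE(cm[i, j] > cor_cutoff) &&
          !(num[i] %in% excluded) && !(num[j] %in% excluded))
        excluded <- c(excluded, num[j])
    }
  }
  keep <- setdiff(covariates, excluded)
  if (nrow(data) < length(keep) + 3L)
    stop("too few complete cases (", nrow(data), ") for stepwise selection over ",
         length(keep), " covariate(s)")
  fml <- stats::as.formula(paste(response, "~",
                                 if (length(keep)) paste(keep, collapse = " + ")
                                 else "1"))
  fit0 <- switch(family,
    logistic = stats::glm(fml, data = data, family = stats::binomial()),
    negative_binomial = MASS::glm.nb(fml, data = data))
  if (!fit0$converged) stop("initial ", family, " fit did not converge")
  trace_txt <- utils::capture.output(
    fit <- stats::step(fit0, direction = "both", trace = 1,
                       scope = list(lower = stats::as.formula(paste(response, "~ 1")),
                                    upper = fml)))
  sm <- summary(fit)
  co <- sm$coefficients
  separation <- FALSE
  coefs <- data.table::data.table(
    term = rownames(co), estimate = co[, 1], ratio = exp(co[, 1]),
    se = co[, 2], p = co[, 4])
  if (family == "logistic") {
    mu <- stats::fitted(fit)
    separation <- isTRUE(any(mu < 1e-8 | mu > 1 - 1e-8, na.rm = TRUE)) ||
      isTRUE(any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    sel <- setdiff(all.vars(stats::formula(fit))[-1], response)
    both_classes <- all(table(data[[response]]) >= 2) &&
      length(unique(data[[response]])) == 2L
    if (separation && length(sel) && both_classes &&
        requireNamespace("glmnet", quietly = TRUE)) {
      # penalized-likelihood fallback: light ridge stabilizes the estimates
      ridge <- tryCatch({
        X <- stats::model.matrix(stats::formula(fit), data = data)[, -1, drop = FALSE]
        rg <- glmnet::glmnet(X, data[[response]], family = "binomial",
                             alpha = 0, lambda = 1e-2)
        bb <- as.numeric(stats::coef(rg))
        data.table::data.table(
          term = c("(Intercept)", colnames(X)), estimate = bb, ratio = exp(bb),
          se = NA_real_, p = NA_real_)
      }, error = function(e) NULL)
      if (!is.null(ridge)) coefs <- ridge
    }
  }
  structure(list(
    model = fit,
    coefficients = coefs,
    selected = setdiff(all.vars(stats::formula(fit))[-1], response),
    aic = stats::AIC(fit),
    trace = trace_txt,
    n_dropped_rows = n_dropped,
    excluded_covariates = excluded,
    separation = separation), class = "kataegis_glm")
}

#' @export
print.kataegis_glm <- function(x, ...) {
  cat("Stepwise GLM; AIC =", format(x$aic, digits = 6), "\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  if (length(x$excluded_covariates))
    cat("excluded (correlation):", paste(x$excluded_covariates, collapse = ", "), "\n")
  if (isTRUE(x$separation)) cat("WARNING: separation detected\n")
  print(x$coefficients)
  invisible(x)
}
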