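# Orthonormal contrast basis spanning the space orthogonal to the constant
# vector (k x (k-1)); built from Helmert contrasts via QR.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sphericity correction factor computed from the covariance matrix of
#' the within-subject cells: the covariance is projected onto an orthonormal
#' contrast basis and epsilon-hat = tr(S)^2 / ((k-1) * tr(S^2)). Equals 1
#' under compound symmetry (sphericity) and is bounded below by 1/(k-1).
#'
#' @param within_cov Square symmetric positive semi-definite matrix: the k x k
#'   covariance of the within-subject cell values (k >= 2).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(within_cov) {
  if (!is.matrix(within_cov) || nrow(within_cov) != ncol(within_cov) ||
      nrow(within_cov) < 2)
    stop("`within_cov` must be a square matrix of dimension >= 2", call. = FALSE)
  if (max(abs(within_cov - t(within_cov))) > 1e-8 * max(1, max(abs(within_cov))))
    stop("`within_cov` must be symmetric", call. = FALSE)
  k <- nrow(within_cov)
  M <- orthonormal_contrasts(k)
  S <- t(M) %*% within_cov %*% M
  tr <- sum(diag(S))
  tr2 <- sum(S * S)              # tr(S %*% S) for symmetric S
  if (tr2 <= 0) return(1)        # degenerate: no within-cell variance
  max(1 / (k - 1), min(1, tr^2 / ((k - 1) * tr2)))
}

# Sum of squared residuals of Y (n x d) on the column space of X, plus the
# extra SS explained by the columns `term` of X over the model without them.
drop_term_ss <- function(Y, X, term_cols) {
  q_full <- qr(X)
  if (q_full$rank < ncol(X))
    stop("singular between-subjects design (rank ", q_full$rank, " < ",
         ncol(X), " columns); check group/sex/covariate coding", call. = FALSE)
  q_red <- qr(X[, -term_cols, drop = FALSE])
  res_full <- qr.resid(q_full, Y)
  res_red <- qr.resid(q_red, Y)
  list(sse = crossprod(res_full),
       ssh = crossprod(res_red) - crossprod(res_full),
       df_err = nrow(X) - q_full$rank)
}

#' Mixed-design repeated-measures ANCOVA
#'
#' The study's omnibus model: group (high/low cognitive function) as the
#' between-subjects factor, electrode ("node") and scale bin as crossed
#' within-subject factors, and age and sex as covariates. Fitted with the
#' univariate mixed-GLM approach: the subjects x cells response matrix is
#' projected onto orthonormal within-subject contrast bases, each stratum is
#' regressed on the between-subjects design (intercept, centered covariates,
#' sum-coded group; Type III drop-term sums of squares), and the four
#' group-related effects are reported with Greenhouse-Geisser-adjusted
#' p-values for the within strata and partial eta^2 =
#' SS_effect / (SS_effect + SS_error).
#'
#' Subjects with any undefined cell are removed listwise (with a message).
#'
#' @param binned A `scale_bin_profile` (subjects x electrodes x bins).
#' @param subjects Data frame with columns `subject_id`, `group` (factor or
#'   character with levels low/high), and the covariate columns; row order
#'   need not match the profile (matched by `subject_id`).
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "sex")`); may be empty for an unadjusted mixed ANOVA.
#' @return Object of class `rm_ancova` with an `effects` data frame (effect,
#'   df1, df2, F, p, gg_epsilon, gg_p, partial_eta2), the per-stratum error
#'   SSP matrices, and the subject count used.
#' @export
fit_rm_ancova <- function(binned, subjects, covariates = c("age", "sex")) {
  stopifnot(inherits(binned, "scale_bin_profile"), is.data.frame(subjects))
  ids <- dimnames(binned)[[1]]
  if (!all(ids %in% subjects$subject_id))
    stop("subjects table is missing id(s): ",
         paste(setdiff(ids, subjects$subject_id), collapse = ", "), call. = FALSE)
  sub <- subjects[match(ids, subjects$subject_id), , drop = FALSE]
  E <- dim(binned)[2]; B <- dim(binned)[3]
  n0 <- dim(binned)[1]
  Y <- matrix(unclass(binned), n0, E * B)     # column (b-1)*E + e
  complete <- stats::complete.cases(Y)
  if (any(!complete))
    message("listwise deletion: dropping ", sum(!complete),
            " subject(s) with undefined cells")
  Y <- Y[complete, , drop = FALSE]
  sub <- sub[complete, , drop = FALSE]
  n <- nrow(Y)
  grp <- factor(sub$group, levels = c("low", "high"))
  if (any(is.na(grp)))
    stop("`group` must contain only 'low' / 'high'", call. = FALSE)
  if (min(table(grp)) < 2)
    stop("need at least 2 subjects per group, got ",
         paste(table(grp), collapse = "/"), call. = FALSE)
  g <- ifelse(grp == "high", 1, -1)           # sum-to-zero coding
  Xc <- NULL
  for (cv in covariates) {
    v <- sub[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found", call. = FALSE)
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1   # binary indicator
    Xc <- cbind(Xc, v - mean(v))
  }
  X <- cbind(1, Xc, g)
  gcol <- ncol(X)

  jE <- rep(1 / sqrt(E), E); jB <- rep(1 / sqrt(B), B)
  CE <- orthonormal_contrasts(E); CB <- orthonormal_contrasts(B)
  strata <- list(
    Group                 = list(M = kronecker(jB, jE), within_df = 0),
    `Group x scale`       = list(M = kronecker(CB, jE), within_df = B - 1),
    `Group x node`        = list(M = kronecker(jB, CE), within_df = E - 1),
    `Node x scale x group` = list(M = kronecker(CB, CE),
                                  within_df = (E - 1) * (B - 1)))
  eff <- data.frame(effect = names(strata), df1 = NA_real_, df2 = NA_real_,
                    F = NA_real_, p = NA_real_, gg_epsilon = NA_real_,
                    gg_p = NA_real_, partial_eta2 = NA_real_)
  ssp <- list()
  for (i in seq_along(strata)) {
    M <- strata[[i]]$M
    d <- max(1L, strata[[i]]$within_df)
    Ystar <- Y %*% M
    ss <- drop_term_ss(Ystar, X, gcol)
    ssh <- sum(diag(as.matrix(ss$ssh)))
    sse <- sum(diag(as.matrix(ss$sse)))
    df1 <- d                                   # 1 (group df) x within df
    df2 <- ss$df_err * d
    Fv <- (ssh / df1) / (sse / df2)
    eff$df1[i] <- df1; eff$df2[i] <- df2; eff$F[i] <- Fv
    eff$p[i] <- pf(Fv, df1, df2, lower.tail = FALSE)
    if (strata[[i]]$within_df > 0) {
      S <- as.matrix(ss$sse)
      tr <- sum(diag(S)); tr2 <- sum(S * S)
      epsv <- if (tr2 <= 0) 1 else max(1 / d, min(1, tr^2 / (d * tr2)))
      eff$gg_epsilon[i] <- epsv
      eff$gg_p[i] <- pf(Fv, epsv * df1, epsv * df2, lower.tail = FALSE)
    } else {
      eff$gg_epsilon[i] <- NA_real_
      eff$gg_p[i] <- eff$p[i]
    }
    eff$partial_eta2[i] <- ssh / (ssh + sse)
    ssp[[names(strata)[i]]] <- as.matrix(ss$sse)
  }
  structure(list(effects = eff, n_subjects = n, n_dropped = sum(!complete),
                 covariates = covariates, error_ssp = ssp,
                 dims = c(electrodes = E, bins = B)),
            class = "rm_ancova")
}

#' @export
print.rm_ancova <- function(x, digits = 4, ...) {
  cat("Mixed-design repeated-measures ANCOVA (", x$n_subjects, " subjects",
      if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped listwise"),
      ")\n", sep = "")
  if (length(x$covariates))
    cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("Within-subject grid:", x$dims[["electrodes"]], "electrodes x",
      x$dims[["bins"]], "scale bins\n\n")
  tab <- x$effects
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rm_ancova <- function(object, ...) {
  print(object, ...)
  cat("\nGreenhouse-Geisser-adjusted p-values apply to within-subject effects.\n")
  invisible(object$effects)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Standard step-up rule: with ordered p-values p_(1) <= ... <= p_(M), find
#' the largest k with p_(k) <= k * q / M; reject every hypothesis with
#' p <= p_(k). The critical p is p_(k) (0 when nothing is rejected).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed; never
#'   rejected, not counted in M).
#' @param q Target false-discovery rate (default 0.05).
#' @return List with `mask` (logical, same length as `pvals`) and
#'   `critical_p`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!is.numeric(pvals)) stop("`pvals` must be numeric", call. = FALSE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- pvals[ok]
  M <- length(p)
  mask <- rep(FALSE, length(pvals))
  if (M == 0) return(list(mask = mask, critical_p = 0))
  ps <- sort(p)
  k <- which(ps <= seq_len(M) * q / M)
  crit <- if (length(k) == 0) 0 else ps[max(k)]
  mask[ok] <- pvals[ok] <= crit & crit > 0
  list(mask = mask, critical_p = crit)
}

# Two-sample t grid over the trailing axes of a subjects x ... array.
group_t_grid <- function(arr, grp, var_equal = TRUE) {
  hi <- which(grp == "high"); lo <- which(grp == "low")
  dims <- dim(arr)[-1]
  tmat <- pmat <- array(NA_real_, dim = dims, dimnames = dimnames(arr)[-1])
  flat <- matrix(arr, dim(arr)[1], prod(dims))
  for (j in seq_len(ncol(flat))) {
    x <- flat[hi, j]; y <- flat[lo, j]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    if (isTRUE(all.equal(c(x, y), rep(c(x, y)[1], length(x) + length(y))))) {
      tmat[j] <- 0; pmat[j] <- 1; next
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tmat[j] <- unname(tt$statistic)     # positive <=> high mean larger
    pmat[j] <- tt$p.value
  }
  list(t = tmat, p = pmat)
}

#' Post-hoc group t-tests over the electrode x scale-bin grid
#'
#' Two-sample t-test (pooled variance by default, Welch optional) per
#' (electrode, scale-bin) cell comparing the high vs. low cognitive-function
#' groups, with Benjamini-Hochberg FDR control over the full grid of
#' hypotheses (19 x 8 = 152 at the default montage and binning). Positive t
#' means the high group mean is larger.
#'
#' @param binned A `scale_bin_profile`.
#' @param subjects Subject table with `subject_id` and `group`.
#' @param q FDR level (default 0.05).
#' @param var_equal Pooled-variance t (default `TRUE`); `FALSE` for Welch.
#' @return Object of class `posthoc_grid`: matrices `t`, `p`, logical `mask`,
#'   plus `critical_p`, `q`, `n_tests` and the axis type.
#' @export
posthoc_ttests <- function(binned, subjects, q = 0.05, var_equal = TRUE) {
  stopifnot(inherits(binned, "scale_bin_profile"))
  grp <- match_groups(binned, subjects)
  res <- group_t_grid(unclass(binned), grp, var_equal)
  fdr <- bh_fdr(as.vector(res$p), q)
  structure(list(t = res$t, p = res$p,
                 mask = array(fdr$mask, dim = dim(res$p), dimnames = dimnames(res$p)),
                 critical_p = fdr$critical_p, q = q,
                 n_tests = sum(!is.na(res$p)), axis = "scale_bin",
                 bins = attr(binned, "bins")),
            class = "posthoc_grid")
}

#' Pointwise group t-tests on the PSD grid
#'
#' The spectral control analysis: a two-sample t-test per (electrode,
#' frequency-point) cell of a `psd_matrix`, with Benjamini-Hochberg FDR over
#' the full grid (19 x 59 = 1121 hypotheses at the default montage and 2-60 Hz
#' / 1 Hz grid).
#'
#' @param psd A `psd_matrix`.
#' @inheritParams posthoc_ttests
#' @return A `posthoc_grid` with axis `"frequency"`.
#' @export
psd_pointwise_tests <- function(psd, subjects, q = 0.05, var_equal = TRUE) {
  stopifnot(inherits(psd, "psd_matrix"))
  grp <- match_groups(psd, subjects)
  res <- group_t_grid(unclass(psd), grp, var_equal)
  fdr <- bh_fdr(as.vector(res$p), q)
  structure(list(t = res$t, p = res$p,
                 mask = array(fdr$mask, dim = dim(res$p), dimnames = dimnames(res$p)),
                 critical_p = fdr$critical_p, q = q,
                 n_tests = sum(!is.na(res$p)), axis = "frequency",
                 freq = attr(psd, "freq")),
            class = "posthoc_grid")
}

match_groups <- function(arr, subjects) {
  ids <- dimnames(arr)[[1]]
  if (!all(ids %in% subjects$subject_id))
    stop("subjects table is missing id(s): ",
         paste(setdiff(ids, subjects$subject_id), collapse = ", "), call. = FALSE)
  grp <- factor(subjects$group[match(ids, subjects$subject_id)],
                levels = c("low", "high"))
  if (any(is.na(grp))) stop("`group` must be 'low' / 'high'", call. = FALSE)
  grp
}

#' @export
print.posthoc_grid <- function(x, ...) {
  cat("<posthoc_grid> ", nrow(x$t), " electrodes x ", ncol(x$t), " ",
      if (x$axis == "scale_bin") "scale bins" else "frequency points",
      " (", x$n_tests, " tests)\n", sep = "")
  cat("BH-FDR q = ", x$q, ": ", sum(x$mask, na.rm = TRUE),
      " discoveries, critical p = ", signif(x$critical_p, 4), "\n", sep = "")
  if (any(x$mask, na.rm = TRUE)) {
    hits <- which(x$mask, arr.ind = TRUE)
    cat("electrodes with discoveries: ",
        paste(sort(unique(rownames(x$t)[hits[, 1]])), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Long-format table of a binned profile with subject covariates
#'
#' @param binned A `scale_bin_profile`.
#' @param subjects Subject table (`subject_id`, `group`, `age`, `sex`, ...).
#' @return Data frame with one row per (subject, electrode, scale_bin) cell:
#'   the input layout of the repeated-measures ANCOVA.
#' @export
make_long_table <- function(binned, subjects) {
  df <- as.data.frame(binned)
  names(df)[names(df) == "bin"] <- "scale_bin"
  idx <- match(df$subject, subjects$subject_id)
  keep <- intersect(c("group", "age", "sex"), names(subjects))
  cbind(subject_id = df$subject, subjects[idx, keep, drop = FALSE],
        df[c("electrode", "scale_bin", "value")], row.names = NULL)
}
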