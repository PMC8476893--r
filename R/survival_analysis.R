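# Survival stratification by signature output: Kaplan-Meier curves with the
# log-rank test, restricted-mean DFS per group, and covariate-adjusted Cox
# models. Fitting is delegated to the survival package (Efron tie handling).

#' Assemble a survival dataset
#'
#' @param group Per-sample group labels (signature labels or the high/low
#'   split), named by sample id or aligned with `pheno`.
#' @param pheno Phenotype data.frame with `sample_id`, `dfs_time` (months),
#'   `dfs_event` (0/1) and optionally `stage`, `age`, `gender`.
#' @return data.frame with `group` attached, rows restricted to samples having
#'   both a group and follow-up, `group` coded as a factor.
#' @export
survival_dataset <- function(group, pheno) {
  if (!all(c("sample_id", "dfs_time", "dfs_event") %in% colnames(pheno)))
    stop("phenotype table needs sample_id, dfs_time and dfs_event")
  if (!is.null(names(group))) {
    idx <- match(pheno$sample_id, names(group))
    group <- group[idx]
  } else if (length(group) != nrow(pheno)) {
    stop("unnamed group vector must align with phenotype rows")
  }
  d <- pheno
  d$group <- as.character(group)
  d <- d[!is.na(d$group) & !is.na(d$dfs_time) & !is.na(d$dfs_event), , drop = FALSE]
  if (any(d$dfs_time < 0)) stop("dfs_time must be >= 0")
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) stop("survival dataset needs at least 2 groups")
  if (any(table(d$group) == 0L)) stop("empty survival group")
  rownames(d) <- NULL
  d
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group, the log-rank statistic and
#' p-value, and the restricted mean survival time (RMST) per group over the
#' common follow-up window -- the only group mean that is well-defined under
#' censoring, used here as the "average DFS time".
#'
#' @param dataset data.frame from [survival_dataset()].
#' @return List: `fit` (a [survival::survfit] object), `chisq`, `p_value`,
#'   `rmean` (named per-group RMST), `rmean_horizon`.
#' @export
km_logrank <- function(dataset) {
  stopifnot(is.factor(dataset$group))
  if (nlevels(droplevels(dataset$group)) < 2L) stop("log-rank needs >= 2 groups")
  if (sum(dataset$dfs_event) == 0L)
    stop("log-rank undefined: no events in any group")
  s <- survival::Surv(dataset$dfs_time, dataset$dfs_event)
  fit <- survival::survfit(s ~ group, data = dataset)
  lr <- survival::survdiff(s ~ group, data = dataset)
  df <- length(lr$n) - 1L
  p <- stats::pchisq(lr$chisq, df = df, lower.tail = FALSE)
  horizon <- max(dataset$dfs_time)
  tab <- summary(fit, rmean = horizon)$table
  rmean <- stats::setNames(tab[, "rmean"], sub("^group=", "", rownames(tab)))
  list(fit = fit, chisq = unname(lr$chisq), p_value = p,
       rmean = rmean, rmean_horizon = horizon)
}

#' Covariate-adjusted Cox model for the signature group
#'
#' Cox proportional-hazards fit (partial likelihood, Efron ties) of DFS on the
#' signature group indicator, adjusted for the requested covariates. The
#' hazard ratio is reported for the *second* factor level of `group` relative
#' to the first (e.g. responder vs non-responder when labels are coded by
#' [normalize_response()], whose factor order puts non-responder first).
#'
#' @param dataset data.frame from [survival_dataset()].
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("stage", "age", "gender")`); stage and gender enter as categorical
#'   indicators, age as continuous. May be empty.
#' @return List: `hr`, `log_hr`, `ci` (Wald 95%), `p_value`, `fit`.
#' @export
cox_adjusted <- function(dataset, covariates = character(0)) {
  miss <- setdiff(covariates, colnames(dataset))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (any(vapply(covariates, function(v) anyNA(dataset[[v]]), logical(1))))
    stop("covariates must be present for all samples")
  n_events <- sum(dataset$dfs_event)
  for (v in covariates) {
    if (is.character(dataset[[v]])) dataset[[v]] <- factor(dataset[[v]])
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  form <- stats::as.formula(paste("survival::Surv(dfs_time, dfs_event) ~", rhs))
  n_par <- 1L + sum(vapply(covariates, function(v)
    if (is.factor(dataset[[v]])) nlevels(dataset[[v]]) - 1L else 1L, integer(1)))
  if (n_events < n_par)
    stop("too few events (", n_events, ") for ", n_par, " parameters")
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(form, data = dataset, ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w)))
          stop("monotone likelihood / complete separation: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)))
  i <- grep("^group", names(stats::coef(fit)))[1L]
  beta <- stats::coef(fit)[i]
  se <- sqrt(diag(stats::vcov(fit)))[i]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stop("monotone likelihood: group log-hazard estimate is unbounded")
  z <- stats::qnorm(0.975)
  list(hr = unname(exp(beta)), log_hr = unname(beta),
       ci = c(low = unname(exp(beta - z * se)), high = unname(exp(beta + z * se))),
       p_value = unname(2 * stats::pnorm(-abs(beta / se))),
       fit = fit)
}
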