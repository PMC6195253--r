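#' Specify a heteroscedastic linear model for a fitness-assay response
#'
#' The model is a Gaussian linear model `y = X beta + Z b + e` with
#' sum-to-zero-coded fixed effects, an optional single random intercept
#' (typically assay block), and a diagonal residual covariance in which every
#' observation's variance is the parameter of its residual group. Residual
#' groups are the cells of the interaction of `resid_group` factors ("pooled"
#' residual variance corresponds to an empty grouping; grouping by
#' `"method"` gives one residual variance per counting method; grouping by
#' all of focal, competitor and method gives one per design cell).
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect term labels: column names of
#'   the data and `:`-interactions among them (e.g.
#'   `c("focal_strain", "method", "focal_strain:method")`). Interactions
#'   require their marginal terms. Empty vector = intercept only.
#' @param random Either `character(0)` (no random term) or the name of one
#'   grouping column for a random intercept (e.g. `"block_id"`).
#' @param resid_group Character vector of factor columns whose interaction
#'   defines the residual-variance groups, or the shorthand `"pooled"`
#'   (single variance). The grouping must partition the design cells.
#' @return An object of class `vm_spec`.
#' @export
vm_spec <- function(response, fixed = character(), random = character(),
                    resid_group = "pooled") {
  stopifnot(is.character(response), length(response) == 1L)
  fixed <- as.character(fixed)
  if (length(resid_group) == 1L && resid_group == "pooled") resid_group <- character()
  if (length(random) > 1L) stop("at most one random intercept term is supported", call. = FALSE)
  # marginality: every interaction requires its lower-order terms
  for (term in fixed[grepl(":", fixed)]) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    need <- unlist(lapply(seq_len(length(parts) - 1L), function(k) {
      utils::combn(parts, k, paste, collapse = ":")
    }))
    need <- unique(c(need, sapply(need, function(s) paste(rev(strsplit(s, ":")[[1L]]), collapse = ":"))))
    present <- vapply(need, function(s) {
      any(vapply(fixed, same_term, logical(1), s))
    }, logical(1))
    if (!all(present)) {
      stop("interaction `", term, "` requires its marginal terms in `fixed`", call. = FALSE)
    }
  }
  structure(list(response = response, fixed = unique(fixed),
                 random = random, resid_group = resid_group),
            class = "vm_spec")
}

same_term <- function(a, b) {
  setequal(strsplit(a, ":", fixed = TRUE)[[1L]], strsplit(b, ":", fixed = TRUE)[[1L]])
}

spec_label <- function(spec) {
  paste0("fixed={", paste(spec$fixed, collapse = ","), "} resid={",
         if (length(spec$resid_group)) paste(spec$resid_group, collapse = ":") else "pooled",
         "}", if (length(spec$random)) paste0(" random=", spec$random) else "")
}

#' @export
print.vm_spec <- function(x, ...) {
  cat("<vm_spec>", x$response, "~", spec_label(x), "\n")
  invisible(x)
}

# Design pieces shared by fitting and F-tests
vm_design <- function(spec, data) {
  if (!spec$response %in% names(data)) {
    stop("response column `", spec$response, "` not found", call. = FALSE)
  }
  y <- data[[spec$response]]
  used <- unique(c(unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$resid_group, spec$random))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(y)
  for (v in used) keep <- keep & !is.na(data[[v]])
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  # deterministic factor coding: sorted unique levels, sum-to-zero contrasts
  fdat <- data
  factor_cols <- setdiff(used, character(0))
  for (v in factor_cols) fdat[[v]] <- factor(as.character(data[[v]]), levels = sort(unique(as.character(data[[v]]))))
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("~", rhs))
  tms <- stats::terms(fml)
  fvars <- intersect(all.vars(fml), names(fdat))
  contr <- stats::setNames(as.list(rep("contr.sum", length(fvars))), fvars)
  X <- stats::model.matrix(fml, data = fdat, contrasts.arg = if (length(fvars)) contr else NULL)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  grp <- if (length(spec$resid_group)) {
    interaction(fdat[spec$resid_group], drop = TRUE, sep = ":")
  } else {
    factor(rep("pooled", n))
  }
  tab <- table(grp)
  if (any(tab < 2L)) {
    stop("each free residual-variance group needs >= 2 observations; offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  blk <- if (length(spec$random)) droplevels(factor(fdat[[spec$random]])) else NULL
  list(y = y, X = X, grp = grp, blk = blk, n = n,
       assign = attr(X, "assign"),
       term_labels = attr(tms, "term.labels"),
       n_dropped = sum(!keep))
}

# Profiled negative twice-log-likelihood (without 2*pi constants) and GLS
# pieces at variance parameters theta = c(log sigma2_group..., log sigma2_block?).
# Uses the Woodbury identity per block: V_l = D_l + s2b * 1 1'.
vm_eval <- function(theta, des, has_block) {
  G <- nlevels(des$grp)
  theta <- pmin(pmax(theta, -30), 30)
  v <- exp(theta[seq_len(G)])
  s2b <- if (has_block) exp(theta[G + 1L]) else 0
  d <- v[as.integer(des$grp)]
  u <- 1 / d
  X <- des$X
  y <- des$y
  Xu <- X * u
  A <- crossprod(X, Xu)
  b <- crossprod(X, y * u)
  logdetV <- sum(log(d))
  if (has_block) {
    s_l <- rowsum(u, des$blk)[, 1L]
    c_l <- s2b / (1 + s2b * s_l)
    T_l <- rowsum(Xu, des$blk)
    ty_l <- rowsum(y * u, des$blk)[, 1L]
    A <- A - crossprod(T_l * sqrt(c_l))
    b <- b - crossprod(T_l, c_l * ty_l)
    logdetV <- logdetV + sum(log1p(s2b * s_l))
  }
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  r <- y - drop(X %*% beta)
  quad <- sum(r^2 * u)
  if (has_block) {
    tr_l <- rowsum(r * u, des$blk)[, 1L]
    quad <- quad - sum(c_l * tr_l^2)
  }
  logdetA <- 2 * sum(log(diag(ch)))
  list(beta = drop(beta), chA = ch, quad = quad,
       logdetV = logdetV, logdetA = logdetA, v = v, s2b = s2b)
}

vm_objective <- function(des, has_block, criterion) {
  n <- des$n
  p <- ncol(des$X)
  function(theta) {
    ev <- vm_eval(theta, des, has_block)
    if (is.null(ev)) return(1e10)
    if (criterion == "REML") {
      ev$logdetV + ev$logdetA + ev$quad
    } else {
      ev$logdetV + ev$quad
    }
  }
}

#' Fit a heteroscedastic linear model by REML or ML
#'
#' Fixed effects are profiled out by generalized least squares at every
#' variance iterate; variance parameters are optimized on the log scale by
#' Nelder-Mead (Brent for a single parameter) from moment-based starting
#' values, so the fit is deterministic given the data. The restricted
#' likelihood adjusts for fixed-effect estimation; ML does not. The REML
#' log-likelihood contains the constant `log|X' V^-1 X|` and therefore
#' depends on the fixed-effect coding (sum-to-zero here); REML values are
#' only comparable between fits sharing one fixed-effect design, which
#' [model_search()] enforces.
#'
#' @param spec A [vm_spec()].
#' @param data Data frame containing the response and all referenced columns.
#'   Rows with missing values in any used column are dropped.
#' @param criterion `"REML"` (default) or `"ML"`.
#' @return An object of class `varmodel_fit` with coefficient estimates,
#'   per-group residual variances, the block-intercept variance (0 when
#'   pinned at the boundary), the log-likelihood (labelled with its
#'   criterion), the AICc parameter count `k`, and convergence diagnostics.
#' @export
fit_varmodel <- function(spec, data, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(spec, "vm_spec"))
  des <- vm_design(spec, data)
  has_block <- !is.null(des$blk)
  G <- nlevels(des$grp)
  # moment starts from OLS residuals
  ols <- stats::lm.fit(des$X, des$y)
  res <- ols$residuals
  v0 <- tapply(res^2, des$grp, function(z) max(mean(z), 1e-12))
  theta0 <- log(as.numeric(v0))
  if (has_block) {
    bm <- tapply(res, des$blk, mean)
    s2b0 <- max(stats::var(as.numeric(bm)) - mean(unlist(v0)) / mean(table(des$blk)), 1e-4 * mean(unlist(v0)))
    theta0 <- c(theta0, log(s2b0))
  }
  obj <- vm_objective(des, has_block, criterion)
  npar <- length(theta0)
  if (npar == 1L) {
    opt <- stats::optim(theta0, obj, method = "Brent",
                        lower = theta0 - 25, upper = theta0 + 25,
                        control = list(reltol = 1e-14))
  } else {
    opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-13,
                                       maxit = max(5000, 2000 * npar)))
    if (npar <= 8L) {
      # polishing restart guards against premature simplex collapse; only
      # low-dimensional fits need (or can reach) near-machine precision
      opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                           control = list(reltol = 1e-13, maxit = 5000))
      if (opt2$value <= opt$value) opt <- opt2
    }
  }
  if (opt$convergence != 0) {
    stop("variance-model fit failed to converge (optim code ", opt$convergence,
         ", objective ", format(opt$value), ", spec ", spec_label(spec), ")",
         call. = FALSE)
  }
  theta_hat <- opt$par
  ev <- vm_eval(theta_hat, des, has_block)
  n <- des$n
  p <- ncol(des$X)
  logLik <- if (criterion == "REML") {
    -0.5 * (opt$value + (n - p) * log(2 * pi))
  } else {
    -0.5 * (opt$value + n * log(2 * pi))
  }
  n_var <- G + as.integer(has_block)
  k <- if (criterion == "ML") p + n_var else n_var
  vcov_beta <- chol2inv(ev$chA)
  dimnames(vcov_beta) <- list(colnames(des$X), colnames(des$X))
  sigma2_block <- if (has_block) {
    if (ev$s2b < 1e-8 * mean(ev$v)) 0 else ev$s2b
  } else {
    NULL
  }
  fit <- structure(list(
    spec = spec, criterion = criterion,
    beta = stats::setNames(ev$beta, colnames(des$X)),
    vcov_beta = vcov_beta,
    sigma2 = stats::setNames(ev$v, levels(des$grp)),
    sigma2_block = sigma2_block,
    logLik = logLik, k = k, n = n, p_fixed = p, n_var = n_var,
    theta = theta_hat,
    assign = des$assign, term_labels = des$term_labels,
    design = des, has_block = has_block,
    convergence = list(code = opt$convergence, objective = opt$value,
                       evaluations = opt$counts[["function"]]),
    n_dropped = des$n_dropped
  ), class = "varmodel_fit")
  fit$aicc <- aicc(fit)
  fit
}

#' @export
print.varmodel_fit <- function(x, ...) {
  cat("<varmodel_fit> ", x$spec$response, " ~ ", spec_label(x$spec), "\n",
      "  criterion: ", x$criterion, "  logLik: ", format(x$logLik),
      "  k: ", x$k, "  n: ", x$n, "  AICc: ", format(x$aicc), "\n", sep = "")
  cat("  residual variances:\n")
  print(signif(x$sigma2, 5))
  if (!is.null(x$sigma2_block)) cat("  block variance:", signif(x$sigma2_block, 5), "\n")
  invisible(x)
}

#' Corrected Akaike information criterion of a fit
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts fixed-effect
#' coefficients plus variance parameters under ML, and variance parameters
#' only under REML (restricted likelihoods of models with different fixed
#' effects are not comparable, so under REML the fixed effects are part of
#' the data transformation, not the parameter count).
#'
#' @param fit A `varmodel_fit`, or a list with elements `logLik`, `k`, `n`.
#' @return The AICc value; `NA` (with a warning) when `n <= k + 1`.
#' @export
aicc <- function(fit) {
  k <- fit$k
  n <- fit$n
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  -2 * fit$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate model structures by AICc
#'
#' Fits every candidate on the same observations and ranks by AICc.
#' Comparisons across different fixed-effect sets are performed under ML;
#' when all candidates share one fixed-effect set (so only the
#' variance structure differs) the comparison is under REML. The criterion
#' actually used is recorded on the result. Candidates that fail to converge
#' are ranked last and flagged, never silently dropped; ties keep input
#' order.
#'
#' @param data Data frame of observations.
#' @param candidates List of [vm_spec()] objects (at least 2).
#' @param criterion Optional override of the automatic REML/ML choice.
#' @return A list: `results` (ranked tibble with AICc, delta-AICc,
#'   convergence flags), `fits` (in input order), `best` (the winning
#'   `varmodel_fit`), `best_spec`, and `criterion`.
#' @export
model_search <- function(data, candidates, criterion = NULL) {
  if (length(candidates) < 2L) stop("need at least 2 candidate specs", call. = FALSE)
  fixed_sets <- lapply(candidates, function(s) sort(s$fixed))
  same_fixed <- all(vapply(fixed_sets, identical, logical(1), fixed_sets[[1L]]))
  if (is.null(criterion)) criterion <- if (same_fixed) "REML" else "ML"
  fits <- lapply(candidates, function(sp) {
    tryCatch(fit_varmodel(sp, data, criterion = criterion),
             error = function(e) structure(list(error = conditionMessage(e), spec = sp),
                                           class = "varmodel_failure"))
  })
  ok <- !vapply(fits, inherits, logical(1), "varmodel_failure")
  aiccs <- ifelse(ok, vapply(fits, function(f) if (inherits(f, "varmodel_fit")) f$aicc else Inf, numeric(1)), Inf)
  rk <- order(aiccs)  # stable: ties and failures keep input order
  results <- tibble::tibble(
    candidate = seq_along(candidates),
    label = vapply(candidates, spec_label, character(1)),
    criterion = criterion,
    converged = ok,
    logLik = ifelse(ok, vapply(fits, function(f) if (inherits(f, "varmodel_fit")) f$logLik else NA_real_, numeric(1)), NA_real_),
    k = ifelse(ok, vapply(fits, function(f) if (inherits(f, "varmodel_fit")) f$k else NA_real_, numeric(1)), NA_real_),
    aicc = ifelse(ok, aiccs, NA_real_)
  )
  results$delta_aicc <- results$aicc - min(results$aicc, na.rm = TRUE)
  results <- results[rk, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)
  best_idx <- rk[1L]
  list(results = results, fits = fits, best = fits[[best_idx]],
       best_spec = candidates[[best_idx]], criterion = criterion)
}

#' Type-III F-test with Satterthwaite denominator degrees of freedom
#'
#' Wald-type F-statistic for all coefficients of one fixed-effect term,
#' marginal to every other term (with sum-to-zero coding this is the type-III
#' hypothesis). The denominator degrees of freedom come from the
#' Satterthwaite approximation: each eigen-contrast of the term's covariance
#' gets `nu_i = 2 lambda_i^2 / (g_i' A g_i)` where `g_i` is the gradient of
#' its variance with respect to the variance parameters and `A` their
#' asymptotic covariance (inverse observed information); the per-contrast
#' dfs are pooled as in the usual multi-degree-of-freedom Satterthwaite
#' formula. Denominator df may be fractional. In the two-group free-variance
#' case this reduces exactly to the Welch-Satterthwaite df.
#'
#' @param fit A `varmodel_fit` (REML fits recommended for testing).
#' @param term A fixed-effect term label present in the fit.
#' @return A tibble of class `f_test_result`: `term`, `f_value`, `num_df`,
#'   `denom_df`, `p_value`.
#' @export
type3_f_test <- function(fit, term) {
  stopifnot(inherits(fit, "varmodel_fit"))
  ti <- which(vapply(fit$term_labels, same_term, logical(1), term))
  if (length(ti) != 1L) {
    stop("term `", term, "` is not a fixed effect of this fit; available: ",
         paste(fit$term_labels, collapse = ", "), call. = FALSE)
  }
  cols <- which(fit$assign == ti)
  q <- length(cols)
  beta <- fit$beta[cols]
  des <- fit$design
  has_block <- fit$has_block
  covC <- function(theta) {
    ev <- vm_eval(theta, des, has_block)
    chol2inv(ev$chA)
  }
  C_hat <- fit$vcov_beta
  M <- C_hat[cols, cols, drop = FALSE]
  Minv <- solve(M)
  f_value <- drop(crossprod(beta, Minv %*% beta)) / q
  # Satterthwaite machinery
  eg <- eigen(M, symmetric = TRUE)
  obj <- vm_objective(des, has_block, fit$criterion)
  H <- numDeriv::hessian(obj, fit$theta)
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  nu <- numeric(q)
  for (i in seq_len(q)) {
    a <- rep(0, length(fit$beta))
    a[cols] <- eg$vectors[, i]
    lam_fun <- function(th) drop(crossprod(a, covC(th) %*% a))
    lam <- eg$values[i]
    if (is.null(A)) {
      nu[i] <- fit$n - fit$p_fixed
    } else {
      g <- numDeriv::grad(lam_fun, fit$theta)
      denom <- drop(crossprod(g, A %*% g))
      nu[i] <- if (denom > 0) 2 * lam^2 / denom else fit$n - fit$p_fixed
    }
  }
  pos <- nu > 2
  if (any(pos)) {
    E <- sum(nu[pos] / (nu[pos] - 2))
    denom_df <- if (E > q) 2 * E / (E - q) else max(1, min(nu))
  } else {
    denom_df <- max(1, min(nu))
  }
  out <- tibble::tibble(
    term = term, f_value = f_value, num_df = q, denom_df = denom_df,
    p_value = stats::pf(f_value, q, denom_df, lower.tail = FALSE)
  )
  class(out) <- c("f_test_result", class(out))
  out
}

#' Candidate model ladder for the method-comparison analyses
#'
#' Builds the default pool of candidate structures: fixed-effect sets from
#' the full factorial model down through dropped interactions and dropped
#' strain main effects (the counting method, the factor under study, is
#' always retained), crossed with residual-variance groupings from one
#' variance per focal x competitor x method cell, through one per method, to
#' fully pooled.
#'
#' @param response Response column name.
#' @param focal,competitor,method Column names of the three design factors.
#' @param random Random-intercept column (`character(0)` for none).
#' @param include_intercept_only Also include the intercept-only fixed set
#'   (drops the method term too); default `FALSE`.
#' @return A list of [vm_spec()] objects.
#' @export
candidate_ladder <- function(response, focal = "focal_strain",
                             competitor = "competitor_strain",
                             method = "method", random = character(),
                             include_intercept_only = FALSE) {
  f <- focal; c_ <- competitor; m <- method
  t_ <- paste(f, c_, sep = ":")
  u_ <- paste(f, m, sep = ":")
  v_ <- paste(c_, m, sep = ":")
  w3 <- paste(f, c_, m, sep = ":")
  fixed_sets <- list(
    c(f, c_, m, t_, u_, v_, w3),
    c(f, c_, m, t_, u_, v_),
    c(f, c_, m, t_),
    c(f, c_, m),
    m
  )
  if (include_intercept_only) fixed_sets <- c(fixed_sets, list(character()))
  groupings <- list(c(f, c_, m), m, "pooled")
  out <- list()
  for (fx in fixed_sets) {
    for (g in groupings) {
      out[[length(out) + 1L]] <- vm_spec(response, fixed = fx, random = random,
                                         resid_group = g)
    }
  }
  out
}

check_design_factors <- function(data, cols) {
  bad <- cols[vapply(cols, function(v) length(unique(data[[v]])) < 2L, logical(1))]
  if (length(bad)) {
    stop("degenerate design: factor(s) with a single level: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Method comparison on the variability scale SD of log(CI)
#'
#' The dependent variable for quantifying variation is the within-block
#' standard deviation of log(CI) of each focal/competitor/method combination
#' (one value per block-group). The analysis proceeds in two model-search
#' stages: the residual-variance grouping is chosen at the full fixed-effect
#' model by REML AICc, then the fixed-effect set is chosen at that grouping
#' by ML AICc; the winning structure is refitted by REML and the counting
#' method is tested by a type-III F with Satterthwaite df.
#'
#' @param observations Plate-observation table spanning at least 2 blocks
#'   and 2 levels of each design factor.
#' @param log_base Base for log(CI).
#' @return A list: `response` (block-group SD table), `search_variance`,
#'   `search_fixed` (the two ranked searches), `best_spec`, `fit` (final
#'   REML fit), `f_test_method`.
#' @export
analyze_sd_logci <- function(observations, log_base = exp(1)) {
  check_design_factors(observations, c("focal_strain", "competitor_strain", "method"))
  if (length(unique(observations$block_id)) < 2L) {
    stop("need at least 2 blocks", call. = FALSE)
  }
  summaries <- group_summaries(observations, metric = "log_ci", log_base = log_base)
  resp <- summaries[summaries$sd_defined, , drop = FALSE]
  resp$sd_log_ci <- resp$sd
  full_fixed <- candidate_ladder("sd_log_ci")[[1L]]$fixed
  groupings <- list(c("focal_strain", "competitor_strain", "method"), "method", "pooled")
  stage1 <- model_search(resp, lapply(groupings, function(g) {
    vm_spec("sd_log_ci", fixed = full_fixed, resid_group = g)
  }))
  best_grouping <- stage1$best_spec$resid_group
  ladder <- candidate_ladder("sd_log_ci")
  keep <- vapply(ladder, function(s) {
    identical(s$resid_group, if (length(best_grouping)) best_grouping else character())
  }, logical(1))
  stage2 <- model_search(resp, ladder[keep])
  best_spec <- stage2$best_spec
  fit <- fit_varmodel(best_spec, resp, criterion = "REML")
  list(
    response = resp,
    search_variance = stage1$results,
    search_fixed = stage2$results,
    best_spec = best_spec,
    fit = fit,
    f_test_method = type3_f_test(fit, "method")
  )
}

#' Method comparison on the focal-frequency scale
#'
#' Repeats the model-search analysis with the replicate-level focal frequency
#' p as the response and assay block as an additional random intercept
#' (replicate nested within block is the unit of observation). Cells absent
#' from the data — e.g. a block in which one method was not run — are simply
#' omitted. A block-variance estimate pinned at the boundary is reported
#' as 0.
#'
#' @inheritParams analyze_sd_logci
#' @return A list with the same shape as [analyze_sd_logci()]'s, the
#'   response being per-replicate `p`.
#' @export
analyze_p <- function(observations) {
  check_design_factors(observations, c("focal_strain", "competitor_strain", "method"))
  if (length(unique(observations$block_id)) < 2L) {
    stop("need at least 2 blocks", call. = FALSE)
  }
  est <- fitness_estimates(observations)
  resp <- est[!is.na(est$p), , drop = FALSE]
  full_fixed <- candidate_ladder("p")[[1L]]$fixed
  groupings <- list(c("focal_strain", "competitor_strain", "method"), "method", "pooled")
  stage1 <- model_search(resp, lapply(groupings, function(g) {
    vm_spec("p", fixed = full_fixed, random = "block_id", resid_group = g)
  }))
  best_grouping <- stage1$best_spec$resid_group
  ladder <- candidate_ladder("p", random = "block_id")
  keep <- vapply(ladder, function(s) {
    identical(s$resid_group, if (length(best_grouping)) best_grouping else character())
  }, logical(1))
  stage2 <- model_search(resp, ladder[keep])
  best_spec <- stage2$best_spec
  fit <- fit_varmodel(best_spec, resp, criterion = "REML")
  list(
    response = resp,
    search_variance = stage1$results,
    search_fixed = stage2$results,
    best_spec = best_spec,
    fit = fit,
    f_test_method = type3_f_test(fit, "method")
  )
}
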