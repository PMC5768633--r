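#' Cluster mice into LH/NLH by k-means (k = 2)
#'
#' Runs k-means with k fixed at 2 on the raw (failures, latency) plane --
#' no feature scaling, so that cluster geometry matches the units of the
#' discriminant score functions -- keeping the best of \code{n_restarts}
#' random initialisations by within-cluster sum of squares. The cluster
#' whose centroid has the larger mean failure count is named LH.
#'
#' @param behavior data.frame with columns \code{mouse_id}, \code{failures},
#'   \code{latency_s}.
#' @param n_restarts number of random restarts (default 50).
#' @param seed integer seed controlling initialisation.
#' @return list of class \code{"cluster_result"}: \code{labels} (named
#'   character vector mouse_id -> "LH"/"NLH"), \code{centroids} (2 x 2
#'   matrix, rows LH/NLH, columns failures/latency_s), \code{inertia}.
#' @export
cluster_mice <- function(behavior, n_restarts = 50L, seed = 1L) {
  x <- as.matrix(behavior[, c("failures", "latency_s")])
  if (nrow(x) < 2) stop("need at least 2 mice")
  if (nrow(unique(x)) < 2)
    stop("all mice have identical (failures, latency); no two clusters exist")
  km <- withr::with_seed(seed,
    stats::kmeans(x, centers = 2L, nstart = n_restarts))
  lh_cluster <- which.max(km$centers[, "failures"])
  lab <- ifelse(km$cluster == lh_cluster, "LH", "NLH")
  centroids <- km$centers[c(lh_cluster, 3L - lh_cluster), , drop = FALSE]
  rownames(centroids) <- c("LH", "NLH")
  structure(list(labels = stats::setNames(lab, behavior$mouse_id),
                 centroids = centroids, inertia = km$tot.withinss),
            class = "cluster_result")
}

#' Fit per-class linear discriminant score functions
#'
#' Gaussian linear discriminant analysis with a shared (pooled within-class)
#' covariance and empirical class priors. Each class c gets a linear score
#' \deqn{s_c(x) = \beta_{0c} + \beta_{1c} \cdot failures +
#'   \beta_{2c} \cdot latency}
#' with \eqn{\beta_c = \Sigma^{-1}\mu_c} and \eqn{\beta_{0c} =
#' -\tfrac12 \mu_c^\top \Sigma^{-1} \mu_c + \log \pi_c}; classification is
#' by the larger score. This yields score functions of the same
#' intercept-plus-two-coefficients shape as the frozen reference model.
#'
#' @param behavior data.frame with columns mouse_id, failures, latency_s.
#' @param labels named character vector mouse_id -> "LH"/"NLH" (both classes
#'   with >= 2 members).
#' @return object of class \code{"discriminant_model"}: a list with one
#'   element per class, each \code{c(intercept, coef_failure, coef_latency)}.
#' @export
fit_discriminant <- function(behavior, labels) {
  lab <- labels[behavior$mouse_id]
  if (anyNA(lab)) stop("labels missing for some mice")
  if (!setequal(unique(lab), c("LH", "NLH")))
    stop("labels must contain exactly the classes LH and NLH")
  if (any(table(lab) < 2)) stop("each class needs >= 2 members")
  x <- as.matrix(behavior[, c("failures", "latency_s")])
  mu <- lapply(split(as.data.frame(x), lab), colMeans)
  n <- table(lab)
  pooled <- Reduce(`+`, lapply(split(as.data.frame(x), lab), function(g) {
    stats::cov(g) * (nrow(g) - 1)
  })) / (nrow(x) - 2)
  inv <- tryCatch(solve(pooled), error = function(e)
    stop("pooled within-class covariance is singular; ",
         "classes are degenerate in the (failures, latency) plane"))
  pri <- as.numeric(n) / nrow(x)
  names(pri) <- names(n)
  model <- lapply(c(LH = "LH", NLH = "NLH"), function(cl) {
    beta <- as.numeric(inv %*% mu[[cl]])
    c(intercept = -0.5 * sum(mu[[cl]] * (inv %*% mu[[cl]])) + log(pri[[cl]]),
      coef_failure = beta[1], coef_latency = beta[2])
  })
  structure(model, class = "discriminant_model")
}

#' Construct a discriminant model from explicit coefficients
#' @param lh,nlh numeric length-3 vectors
#'   \code{c(intercept, coef_failure, coef_latency)}.
#' @return a \code{"discriminant_model"}.
#' @export
discriminant_model <- function(lh, nlh) {
  stopifnot(length(lh) == 3, length(nlh) == 3,
            all(is.finite(c(lh, nlh))))
  nm <- c("intercept", "coef_failure", "coef_latency")
  structure(list(LH = stats::setNames(as.numeric(lh), nm),
                 NLH = stats::setNames(as.numeric(nlh), nm)),
            class = "discriminant_model")
}

#' The frozen reference discriminant model
#'
#' The published score equations calibrated on a 31-mouse shuttle-box
#' cohort:
#' \deqn{LH = -24.75 + 0.23 \cdot failures + 4.79 \cdot latency}
#' \deqn{NLH = -15.34 - 2.78 \cdot failures + 10.31 \cdot latency}
#' A mouse is called LH when its LH score strictly exceeds its NLH score.
#' @return a \code{"discriminant_model"}.
#' @export
reference_discriminant <- function() {
  discriminant_model(lh = c(-24.75, 0.23, 4.79),
                     nlh = c(-15.34, -2.78, 10.31))
}

#' Score and classify mice with a discriminant model
#'
#' Evaluates both per-class linear scores and assigns the argmax class;
#' exact ties go to NLH (helplessness is not over-called).
#'
#' @param model a \code{"discriminant_model"}.
#' @param failures,latency numeric vectors (recycled together).
#' @return data.frame with columns failures, latency, score_lh, score_nlh,
#'   class.
#' @export
classify_mice <- function(model, failures, latency) {
  stopifnot(inherits(model, "discriminant_model"),
            all(is.finite(failures)), all(is.finite(latency)))
  s <- function(cf) unname(cf[1] + cf[2] * failures + cf[3] * latency)
  score_lh <- s(model$LH)
  score_nlh <- s(model$NLH)
  data.frame(failures = failures, latency = latency,
             score_lh = score_lh, score_nlh = score_nlh,
             class = ifelse(score_lh > score_nlh, "LH", "NLH"),
             stringsAsFactors = FALSE)
}

#' Group statistics: one-way ANOVA with Bonferroni post hoc tests
#'
#' For each behavioral metric (failures, latency), a one-way ANOVA across
#' all groups followed by all pairwise two-sided pooled-variance t-tests
#' with Bonferroni multiplication (capped at 1).
#'
#' @param behavior data.frame with failures and latency_s columns.
#' @param groups character vector of group memberships, aligned to the rows
#'   of \code{behavior}; each group needs >= 2 members.
#' @return list per metric with \code{means} (group means), \code{sem},
#'   \code{F}, \code{p}, and \code{pairwise} (data.frame group1, group2,
#'   p_raw, p_adj).
#' @export
compare_groups <- function(behavior, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2))
    stop("group(s) with < 2 members: ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  one_metric <- function(y) {
    fit <- stats::aov(y ~ factor(groups))
    av <- summary(fit)[[1]]
    Fv <- av[1, "F value"]
    pv <- av[1, "Pr(>F)"]
    if (is.nan(Fv)) { Fv <- 0; pv <- 1 }
    gl <- split(y, groups)
    pairs <- utils::combn(names(gl), 2)
    n_comp <- ncol(pairs)
    pw <- apply(pairs, 2, function(pr) {
      tt <- stats::t.test(gl[[pr[1]]], gl[[pr[2]]], var.equal = TRUE)
      tt$p.value
    })
    list(means = vapply(gl, mean, 0),
         sem = vapply(gl, function(v) stats::sd(v) / sqrt(length(v)), 0),
         F = Fv, p = pv,
         pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                               p_raw = pw, p_adj = pmin(1, pw * n_comp)))
  }
  list(failures = one_metric(behavior$failures),
       latency = one_metric(behavior$latency_s))
}
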