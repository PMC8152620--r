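# DP4 core: shift-prediction error models (single Gaussian or Gaussian
# mixture), per-error probability densities, and the Bayesian DP4
# probability over candidate structures.

#' Construct a shift-prediction error model
#'
#' @param nucleus `"1H"` or `"13C"`.
#' @param means,sds,weights component parameters (ppm; weights positive,
#'   normalized to sum to one).
#' @return an object of class `ErrorModel` with `kind` `"single_gaussian"`
#'   or `"gaussian_mixture"`.
#' @export
error_model <- function(nucleus = c("13C", "1H"), means = 0, sds,
                        weights = rep(1, length(means))) {
  nucleus <- match.arg(nucleus)
  stopifnot(length(means) == length(sds), length(sds) == length(weights),
            all(sds > 0), all(weights > 0))
  weights <- weights / sum(weights)
  structure(list(nucleus = nucleus, means = means, sds = sds,
                 weights = weights,
                 kind = if (length(means) == 1L) "single_gaussian"
                        else "gaussian_mixture"),
            class = "ErrorModel")
}

#' Default error models
#'
#' Conventional single-Gaussian DP4 parameters: sd 2.3 ppm for 13C,
#' 0.19 ppm for 1H, zero mean. Replace with fitted mixture models via
#' [fit_error_model()] when an empirical error set is available.
#'
#' @param nucleus `"1H"` or `"13C"`.
#' @return an [error_model()].
#' @export
default_error_model <- function(nucleus = c("13C", "1H")) {
  nucleus <- match.arg(nucleus)
  if (nucleus == "13C") error_model("13C", 0, 2.3)
  else error_model("1H", 0, 0.19)
}

#' @export
print.ErrorModel <- function(x, ...) {
  cat(sprintf("<ErrorModel> %s, %s: %s\n", x$nucleus, x$kind,
              paste(sprintf("N(%.3g, %.3g) w=%.3g", x$means, x$sds,
                            x$weights), collapse = " + ")))
  invisible(x)
}

#' Probability density of a shift-prediction error
#'
#' @param error numeric vector of errors, ppm.
#' @param model an [error_model()].
#' @return mixture normal density at each error.
#' @export
error_pdf <- function(error, model) {
  stopifnot(inherits(model, "ErrorModel"))
  out <- numeric(length(error))
  for (c in seq_along(model$means))
    out <- out + model$weights[c] * dnorm(error, model$means[c], model$sds[c])
  out
}

#' Bayesian DP4 probability over candidate structures
#'
#' Per candidate the log-likelihood is the sum over nuclei and atoms of the
#' log error density; with a flat prior over candidates (one of them is
#' assumed correct) the DP4 probability is the softmax of the
#' log-likelihoods, computed in log space.
#'
#' @param errors named list, one element per candidate; each element a list
#'   with components `"1H"` and/or `"13C"` holding numeric error vectors
#'   (ppm). All candidates must cover the same nuclei.
#' @param models list with elements `"1H"`/`"13C"`, each an
#'   [error_model()].
#' @return an object of class `DP4Result`: data.frame with columns
#'   `candidate`, `loglik_1H`, `loglik_13C`, `dp4_1H`, `dp4_13C`,
#'   `dp4` (combined probability; columns for unused nuclei are NA).
#' @export
dp4 <- function(errors, models = list(`1H` = default_error_model("1H"),
                                      `13C` = default_error_model("13C"))) {
  stopifnot(length(errors) >= 1L)
  ids <- names(errors)
  if (is.null(ids)) ids <- paste0("candidate", seq_along(errors))
  nuclei <- unique(unlist(lapply(errors, names)))
  nuclei <- intersect(c("1H", "13C"), nuclei)
  if (!length(nuclei)) stop("no nuclei present in the error lists")
  for (nuc in nuclei) {
    has <- vapply(errors, function(e) !is.null(e[[nuc]]), logical(1))
    if (!all(has))
      stop("every candidate must carry errors for nucleus ", nuc)
  }
  ll <- sapply(nuclei, function(nuc) {
    vapply(errors, function(e) {
      dens <- error_pdf(e[[nuc]], models[[nuc]])
      if (any(dens <= 0)) {
        warning("zero error density floored at 1e-300")
        dens <- pmax(dens, 1e-300)
      }
      sum(log(dens))
    }, numeric(1))
  })
  ll <- matrix(ll, nrow = length(errors),
               dimnames = list(ids, nuclei))
  softmax <- function(v) {
    z <- v - max(v)
    exp(z) / sum(exp(z))
  }
  out <- data.frame(candidate = ids,
                    loglik_1H = if ("1H" %in% nuclei) ll[, "1H"] else NA_real_,
                    loglik_13C = if ("13C" %in% nuclei) ll[, "13C"] else NA_real_,
                    row.names = NULL)
  out$loglik_1H <- unname(out$loglik_1H)
  out$loglik_13C <- unname(out$loglik_13C)
  out$dp4_1H <- if ("1H" %in% nuclei) unname(softmax(out$loglik_1H)) else NA_real_
  out$dp4_13C <- if ("13C" %in% nuclei) unname(softmax(out$loglik_13C)) else NA_real_
  total <- rowSums(ll[, nuclei, drop = FALSE])
  out$dp4 <- unname(softmax(total))
  class(out) <- c("DP4Result", "data.frame")
  out
}

#' @export
print.DP4Result <- function(x, digits = 4, ...) {
  cat("DP4 probabilities:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Fit a Gaussian-mixture error model to empirical prediction errors
#'
#' Maximum-likelihood EM fit (via mclust, unequal-variance 1-D model).
#' With `groups` given, additionally returns leave-one-group-out refits for
#' cross-validation.
#'
#' @param errors numeric vector of observed prediction errors, ppm.
#' @param n_components number of Gaussian components.
#' @param nucleus nucleus label stored on the model.
#' @param seed RNG seed (the EM initialization is deterministic; the seed
#'   guards any subsampling done by the initializer).
#' @param groups optional factor for leave-one-group-out refitting.
#' @return an [error_model()]; with `groups`, attribute `"logo"` holds a
#'   named list of models, each fitted with one group left out. Degenerate
#'   component sds are floored at 1e-3 ppm.
#' @export
fit_error_model <- function(errors, n_components = 3L,
                            nucleus = c("13C", "1H"), seed = 1L,
                            groups = NULL) {
  nucleus <- match.arg(nucleus)
  if (length(errors) < 10L * n_components)
    stop("need at least ", 10L * n_components, " errors to fit ",
         n_components, " components")
  fit_one <- function(e) {
    set.seed(seed)
    fit <- Mclust(e, G = n_components, modelNames = "V", verbose = FALSE)
    if (is.null(fit))
      stop("mixture fit failed for ", n_components, " components")
    p <- fit$parameters
    sds <- sqrt(as.numeric(p$variance$sigmasq))
    if (length(sds) == 1L) sds <- rep(sds, n_components)
    sds <- pmax(sds, 1e-3)
    error_model(nucleus, means = as.numeric(p$mean), sds = sds,
                weights = as.numeric(p$pro))
  }
  model <- fit_one(errors)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    logo <- lapply(levels(groups), function(g) fit_one(errors[groups != g]))
    names(logo) <- levels(groups)
    attr(model, "logo") <- logo
  }
  model
}

#' Draw random errors from an error model
#'
#' @param n number of draws.
#' @param model an [error_model()].
#' @return numeric vector of errors, ppm.
#' @export
sample_errors <- function(n, model) {
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  rnorm(n, model$means[comp], model$sds[comp])
}
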