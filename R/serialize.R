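#' Serialize a Kriging surrogate to a self-describing JSON file
#'
#' Writes everything needed to rebuild the fit exactly: the scaling bounds,
#' the original-space training data, and the estimated `beta`, `sigma2`,
#' `theta` and nugget.  [read_kriging()] reconstructs the model with the
#' stored `theta` (no re-search), so predictions are reproducible across
#' sessions.
#'
#' @param model A fitted [kriging()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kriging <- function(model, path) {
  stopifnot(inherits(model, "kriging"))
  payload <- list(
    format = "stentkrig-kriging",
    version = 1L,
    m = ncol(model$x),
    n = length(model$y),
    lower = model$lower,
    upper = model$upper,
    x = model$x,
    y = model$y,
    beta = model$beta,
    sigma2 = model$sigma2,
    theta = model$theta,
    per_dim_theta = model$per_dim_theta,
    nugget = model$nugget,
    degenerate = isTRUE(model$degenerate)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a Kriging surrogate from its serialized form
#'
#' @param path A file written by [write_kriging()].
#' @return A [kriging()] model equivalent to the serialized one.
#' @export
read_kriging <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "stentkrig-kriging") {
    stop(sprintf("'%s' is not a serialized Kriging model", path), call. = FALSE)
  }
  x <- p$x
  if (!is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  storage.mode(x) <- "double"
  model <- kriging(x, as.numeric(p$y),
                   bounds = list(lower = p$lower, upper = p$upper),
                   theta = as.numeric(p$theta),
                   per_dim_theta = isTRUE(p$per_dim_theta),
                   nugget = p$nugget)
  model
}
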