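# Versioned model container.
#
# A fitted model is stored as one hierarchical, self-describing R
# serialization (RDS, format version 3, gzip): dimension names, all
# variational posteriors, training options and trace, the variance
# decomposition, and (optionally) the raw data blocks with their masks.
# Writing is bit-stable given identical inputs (no timestamps), and the
# serialization format is platform independent (fixed endianness).  The
# loader refuses containers whose major format version it does not know.

SGFA_FORMAT_VERSION <- "1.0"

#' Save a fitted model
#'
#' @param object A fitted `"sgfa"` model.
#' @param path Output file path.
#' @param include_data Store the raw data blocks and masks so that
#'   variance decomposition and ELBO recomputation remain possible after
#'   loading (default `TRUE`).
#' @return `path`, invisibly.
#' @seealso [read_sgfa()]
#' @export
write_sgfa <- function(object, path, include_data = TRUE) {
  stopifnot(inherits(object, "sgfa"))
  container <- list(
    format_version = SGFA_FORMAT_VERSION,
    writer = "sgfa",
    dims = list(groups = object$data$groups, views = object$data$views,
                samples = object$data$samples, features = object$data$features,
                likelihoods = object$data$likelihoods, K = object$K),
    state = object$state,
    trace = object$trace,
    control = object$control,
    variance_explained = object$r2,
    elbo = object$elbo,
    converged = object$converged,
    mode = object$mode,
    feature_means = object$data$feature_means,
    centered = object$data$centered,
    data = if (include_data) list(blocks = object$data$blocks,
                                  masks = object$data$masks) else NULL
  )
  saveRDS(container, path, version = 3)
  invisible(path)
}

#' Load a fitted model
#'
#' Reconstructs the fitted model from a container written by
#' [write_sgfa()].  Containers saved without data still support weight
#' and factor queries; operations that need the data (variance
#' decomposition, ELBO recomputation) are rejected with an explanatory
#' error.
#'
#' @param path Path to a model container.
#' @return An object of class `"sgfa"`.
#' @export
read_sgfa <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$format_version) || !identical(x$writer, "sgfa")) {
    stop("not an sgfa model container: ", path)
  }
  major <- strsplit(x$format_version, ".", fixed = TRUE)[[1L]][1L]
  if (!identical(major, strsplit(SGFA_FORMAT_VERSION, ".", fixed = TRUE)[[1L]][1L])) {
    stop(sprintf("unsupported container version %s (supported: %s)",
                 x$format_version, SGFA_FORMAT_VERSION))
  }
  required <- c("state", "dims", "trace")
  miss <- setdiff(required, names(x)[!vapply(x, is.null, TRUE)])
  if (length(miss)) {
    stop("container is missing required component(s): ", paste(miss, collapse = ", "))
  }
  data <- NULL
  if (!is.null(x$data)) {
    data <- structure(list(
      groups = x$dims$groups, views = x$dims$views,
      samples = x$dims$samples, features = x$dims$features,
      likelihoods = x$dims$likelihoods,
      blocks = x$data$blocks, masks = x$data$masks,
      centered = x$centered, feature_means = x$feature_means
    ), class = "sgfa_data")
  } else {
    # minimal stub carrying names so weight/factor queries keep working
    data <- structure(list(
      groups = x$dims$groups, views = x$dims$views,
      samples = x$dims$samples, features = x$dims$features,
      likelihoods = x$dims$likelihoods,
      blocks = NULL, masks = NULL,
      centered = x$centered, feature_means = x$feature_means
    ), class = "sgfa_data")
  }
  structure(list(
    state = x$state,
    trace = x$trace,
    data = data,
    K = x$dims$K,
    control = x$control,
    elbo = x$elbo,
    converged = x$converged,
    mode = x$mode,
    r2 = x$variance_explained,
    call = NULL
  ), class = "sgfa")
}
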