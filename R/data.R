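#' Assemble a multi-group, multi-view data set
#'
#' Builds the input container for [sgfa()].  Data can be supplied either as
#' a long-format table with columns `sample`, `group`, `feature`, `view`,
#' `value` (one row per observed entry; `NA` values are treated as
#' unobserved), or as a nested list of matrices `blocks[[group]][[view]]`
#' with samples in rows and features in columns (`NA` entries are
#' unobserved).
#'
#' Views partition the features (a feature belongs to exactly one view) and
#' groups partition the samples.  Within each (group, view) block an
#' explicit logical mask records which entries were observed; values at
#' unobserved positions are never used by any computation in the package.
#'
#' @param x A long-format `data.frame` or a nested list of matrices
#'   (`x[[group]][[view]]`).
#' @param likelihoods Named character vector, one of `"gaussian"`,
#'   `"bernoulli"`, `"poisson"` per view.  Defaults to `"gaussian"` for
#'   every view.
#' @return An object of class `sgfa_data`: a list with elements `groups`,
#'   `views`, `samples`, `features`, `likelihoods`, `blocks`, `masks`,
#'   `centered`, `feature_means`.
#' @examples
#' tab <- data.frame(
#'   sample = c("s1", "s1", "s2", "s2", "s2"),
#'   group = "g1",
#'   feature = c("f1", "f2", "f1", "f2", "f3"),
#'   view = "rna",
#'   value = c(1, 2, 3, 4, 5)
#' )
#' ds <- sgfa_data(tab)
#' dim(ds$blocks[[1]][[1]])  # 2 x 3, one unobserved entry
#' @export
sgfa_data <- function(x, likelihoods = NULL) {
  if (is.data.frame(x)) {
    ds <- assemble_long(x)
  } else if (is.list(x)) {
    ds <- assemble_blocks(x)
  } else {
    stop("`x` must be a long-format data.frame or a nested list of matrices")
  }
  if (is.null(likelihoods)) {
    likelihoods <- stats::setNames(rep("gaussian", length(ds$views)), ds$views)
  }
  likelihoods <- check_likelihoods(likelihoods, ds$views)
  ds$likelihoods <- likelihoods
  validate_support(ds)
  ds
}

assemble_long <- function(tab) {
  required <- c("sample", "group", "feature", "view", "value")
  if (!all(required %in% names(tab))) {
    stop("long table must have columns ", paste(required, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("empty input table")
  tab$sample <- as.character(tab$sample)
  tab$group <- as.character(tab$group)
  tab$feature <- as.character(tab$feature)
  tab$view <- as.character(tab$view)
  tab$value <- as.numeric(tab$value)

  key <- paste(tab$sample, tab$group, tab$feature, tab$view, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate entry for sample '%s', feature '%s' (group '%s', view '%s')",
                 d$sample, d$feature, d$group, d$view))
  }
  fv <- unique(tab[, c("feature", "view")])
  if (anyDuplicated(fv$feature)) {
    f <- fv$feature[duplicated(fv$feature)][1L]
    stop(sprintf("feature '%s' is assigned to more than one view", f))
  }
  sg <- unique(tab[, c("sample", "group")])
  if (anyDuplicated(sg$sample)) {
    s <- sg$sample[duplicated(sg$sample)][1L]
    stop(sprintf("sample '%s' is assigned to more than one group", s))
  }

  # canonical (sorted) label order makes assembly invariant to row order
  groups <- sort(unique(tab$group))
  views <- sort(unique(tab$view))
  samples <- lapply(groups, function(g) sort(unique(tab$sample[tab$group == g])))
  names(samples) <- groups
  features <- lapply(views, function(v) sort(unique(tab$feature[tab$view == v])))
  names(features) <- views

  blocks <- masks <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    blocks[[g]] <- masks[[g]] <- stats::setNames(vector("list", length(views)), views)
    for (v in views) {
      sn <- samples[[g]]; fn <- features[[v]]
      B <- matrix(0, length(sn), length(fn), dimnames = list(sn, fn))
      M <- matrix(FALSE, length(sn), length(fn), dimnames = list(sn, fn))
      sel <- tab$group == g & tab$view == v
      if (any(sel)) {
        ij <- cbind(match(tab$sample[sel], sn), match(tab$feature[sel], fn))
        val <- tab$value[sel]
        obs <- !is.na(val)
        B[ij[obs, , drop = FALSE]] <- val[obs]
        M[ij[obs, , drop = FALSE]] <- TRUE
      }
      blocks[[g]][[v]] <- B
      masks[[g]][[v]] <- M
    }
  }
  new_sgfa_data(groups, views, samples, features, blocks, masks)
}

assemble_blocks <- function(blocks) {
  groups <- names(blocks)
  if (is.null(groups) || anyDuplicated(groups)) {
    stop("blocks must be a named list: blocks[[group]][[view]]")
  }
  views <- names(blocks[[1L]])
  if (is.null(views) || anyDuplicated(views)) {
    stop("each group entry must be a named list of view matrices")
  }
  samples <- features <- list()
  out_b <- out_m <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    if (!identical(names(blocks[[g]]), views)) {
      stop("all groups must contain the same views in the same order")
    }
    out_b[[g]] <- out_m[[g]] <- stats::setNames(vector("list", length(views)), views)
    for (v in views) {
      B <- as.matrix(blocks[[g]][[v]])
      if (is.null(rownames(B))) rownames(B) <- paste0(g, "_s", seq_len(nrow(B)))
      if (is.null(colnames(B))) colnames(B) <- paste0(v, "_f", seq_len(ncol(B)))
      if (is.null(samples[[g]])) samples[[g]] <- rownames(B)
      if (is.null(features[[v]])) features[[v]] <- colnames(B)
      if (!identical(rownames(B), samples[[g]])) {
        stop(sprintf("sample names disagree across views in group '%s'", g))
      }
      if (!identical(colnames(B), features[[v]])) {
        stop(sprintf("feature names disagree across groups in view '%s'", v))
      }
      M <- !is.na(B)
      B[!M] <- 0
      out_b[[g]][[v]] <- B
      out_m[[g]][[v]] <- M
    }
  }
  new_sgfa_data(groups, views, samples, features, out_b, out_m)
}

new_sgfa_data <- function(groups, views, samples, features, blocks, masks) {
  if (anyDuplicated(unlist(features))) {
    stop("feature names must be disjoint across views")
  }
  if (anyDuplicated(unlist(samples))) {
    stop("sample names must be disjoint across groups")
  }
  structure(list(
    groups = groups, views = views,
    samples = samples, features = features,
    likelihoods = NULL,
    blocks = blocks, masks = masks,
    centered = stats::setNames(rep(FALSE, length(views)), views),
    feature_means = NULL
  ), class = "sgfa_data")
}

check_likelihoods <- function(lik, views) {
  allowed <- c("gaussian", "bernoulli", "poisson")
  if (length(lik) == 1L && is.null(names(lik))) {
    lik <- stats::setNames(rep(lik, length(views)), views)
  }
  if (is.null(names(lik)) && length(lik) == length(views)) names(lik) <- views
  if (!all(views %in% names(lik))) stop("a likelihood must be given for every view")
  lik <- lik[views]
  bad <- setdiff(lik, allowed)
  if (length(bad)) stop("unknown likelihood: ", paste(bad, collapse = ", "))
  lik
}

validate_support <- function(ds) {
  for (g in ds$groups) for (v in ds$views) {
    y <- ds$blocks[[g]][[v]][ds$masks[[g]][[v]]]
    if (ds$likelihoods[[v]] == "bernoulli" && length(y) && !all(y %in% c(0, 1))) {
      stop(sprintf("bernoulli view '%s' contains observed values outside {0,1}", v))
    }
    if (ds$likelihoods[[v]] == "poisson" && length(y) &&
        (any(y < 0) || any(y != round(y)))) {
      stop(sprintf("poisson view '%s' contains negative or non-integer observed values", v))
    }
  }
  invisible(ds)
}

#' @export
print.sgfa_data <- function(x, ...) {
  cat("Multi-group, multi-view data set\n")
  cat(sprintf("  %d group(s): %s\n", length(x$groups),
              paste(sprintf("%s (n=%d)", x$groups, vapply(x$samples, length, 1L)),
                    collapse = ", ")))
  cat(sprintf("  %d view(s):  %s\n", length(x$views),
              paste(sprintf("%s (d=%d, %s)", x$views,
                            vapply(x$features, length, 1L),
                            x$likelihoods[x$views]), collapse = ", ")))
  obs <- sum(vapply(x$masks, function(g) sum(vapply(g, sum, 0)), 0))
  tot <- sum(vapply(x$groups, function(g) sum(vapply(x$views, function(v)
    length(x$masks[[g]][[v]]), 0)), 0))
  cat(sprintf("  observed entries: %d of %d (%.1f%%)\n", obs, tot, 100 * obs / tot))
  invisible(x)
}

#' Export a data set to long format
#'
#' Returns one row per *observed* entry with columns `sample`, `group`,
#' `feature`, `view`, `value`.  Re-assembling the result with [sgfa_data()]
#' reproduces the original data set.
#'
#' @param x An `sgfa_data` object.
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @export
as.data.frame.sgfa_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- list()
  for (g in x$groups) for (v in x$views) {
    M <- x$masks[[g]][[v]]
    if (!any(M)) next
    idx <- which(M, arr.ind = TRUE)
    out[[paste(g, v)]] <- data.frame(
      sample = rownames(M)[idx[, 1L]],
      group = g,
      feature = colnames(M)[idx[, 2L]],
      view = v,
      value = x$blocks[[g]][[v]][idx],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Center features per group
#'
#' Subtracts, for every Gaussian view, the per-group per-feature mean of the
#' observed entries, so that intercept (mean level) differences between
#' groups are removed before fitting.  Bernoulli and Poisson views are left
#' untouched (centering would break their support).  Features without any
#' observed entry in a group are left as-is and recorded in the
#' `uncentered` attribute.
#'
#' @param ds An `sgfa_data` object.
#' @return The centered data set; removed means are stored in
#'   `ds$feature_means[[group]][[view]]` so reconstructions can add them
#'   back.
#' @export
center_per_group <- function(ds) {
  stopifnot(inherits(ds, "sgfa_data"))
  gauss <- names(ds$likelihoods)[ds$likelihoods == "gaussian"]
  if (length(gauss) == 0L) return(ds)  # nothing to center
  if (all(ds$centered[gauss])) {
    warning("data set is already centered; returning unchanged")
    return(ds)
  }
  if (is.null(ds$feature_means)) {
    ds$feature_means <- stats::setNames(vector("list", length(ds$groups)), ds$groups)
  }
  uncentered <- list()
  for (g in ds$groups) {
    if (is.null(ds$feature_means[[g]])) {
      ds$feature_means[[g]] <- stats::setNames(vector("list", length(ds$views)), ds$views)
    }
    for (v in ds$views) {
      if (!(v %in% gauss)) next
      B <- ds$blocks[[g]][[v]]; M <- ds$masks[[g]][[v]]
      nobs <- colSums(M)
      mu <- ifelse(nobs > 0, colSums(B * M) / pmax(nobs, 1L), 0)
      empty <- nobs == 0L
      if (any(empty)) {
        uncentered[[paste(g, v, sep = "/")]] <- colnames(B)[empty]
      }
      ds$blocks[[g]][[v]] <- sweep(B, 2L, mu, "-")
      # entries of all-unobserved features stay untouched
      if (any(empty)) ds$blocks[[g]][[v]][, empty] <- B[, empty]
      ds$feature_means[[g]][[v]] <- mu
    }
  }
  ds$centered[gauss] <- TRUE
  attr(ds, "uncentered") <- uncentered
  ds
}

#' Keep the most variable features per view
#'
#' Feature variance is computed over all observed entries pooled across
#' groups, after per-group centering of Gaussian views, so that mean
#' differences between groups do not dominate the selection.  Ties are
#' broken in favour of the earlier feature; the retained features keep
#' their original order.
#'
#' @param ds An `sgfa_data` object.
#' @param n Number of features to keep: a single integer or a named vector
#'   per view.  `n >=` the view size keeps all features.
#' @export
select_hvf <- function(ds, n) {
  stopifnot(inherits(ds, "sgfa_data"))
  if (is.null(names(n))) {
    n <- stats::setNames(rep(n, length.out = length(ds$views)), ds$views)
  }
  if (any(n[ds$views] <= 0) || any(is.na(n[ds$views]))) {
    stop("`n` must be a positive count for every view")
  }
  # variances on a per-group-centered copy (gaussian views only)
  cds <- if (all(ds$centered[names(ds$likelihoods)[ds$likelihoods == "gaussian"]])) {
    ds
  } else {
    suppressWarnings(center_per_group(ds))
  }
  for (v in ds$views) {
    D <- length(ds$features[[v]])
    keep_n <- min(as.integer(n[[v]]), D)
    sum1 <- sum2 <- cnt <- numeric(D)
    for (g in ds$groups) {
      B <- cds$blocks[[g]][[v]]; M <- cds$masks[[g]][[v]]
      sum1 <- sum1 + colSums(B * M)
      sum2 <- sum2 + colSums(B * B * M)
      cnt <- cnt + colSums(M)
    }
    mu <- ifelse(cnt > 0, sum1 / pmax(cnt, 1), 0)
    v_d <- ifelse(cnt > 1, (sum2 - cnt * mu^2) / (cnt - 1), 0)
    keep <- sort(order(-v_d)[seq_len(keep_n)])  # stable order(): ties keep earlier index
    ds$features[[v]] <- ds$features[[v]][keep]
    for (g in ds$groups) {
      ds$blocks[[g]][[v]] <- ds$blocks[[g]][[v]][, keep, drop = FALSE]
      ds$masks[[g]][[v]] <- ds$masks[[g]][[v]][, keep, drop = FALSE]
      if (!is.null(ds$feature_means[[g]][[v]])) {
        ds$feature_means[[g]][[v]] <- ds$feature_means[[g]][[v]][keep]
      }
    }
  }
  ds
}

#' Binomial rate and M-value from coverage counts
#'
#' Computes the maximum-likelihood methylation/accessibility rate
#' `successes / trials` per genomic feature and converts it to an M-value,
#' `log2(rate / (1 - rate))`.  Features whose coverage falls below
#' `min_trials` are reported as `NA` (the usual coverage filters are at
#' least 3 CpG measurements, 10 CpH measurements, or 5 GpC measurements,
#' depending on the sequence context).  Rates are clamped to
#' `[eps, 1 - eps]` so the transform stays finite at rate 0 or 1.
#'
#' @param successes,trials Integer vectors of supporting and total read
#'   counts (recycled against each other).
#' @param min_trials Minimum coverage required to report a value.
#' @param eps Clamping constant for the rate.
#' @return Numeric vector of M-values, `NA` where coverage is insufficient.
#' @examples
#' mvalue(5, 10)          # rate 0.5 -> M = 0
#' mvalue(2, 2)           # below default coverage filter -> NA
#' mvalue(3, 4)           # log2(0.75/0.25) = log2(3)
#' @export
mvalue <- function(successes, trials, min_trials = 3L, eps = 0.001) {
  if (min_trials < 1L) stop("`min_trials` must be >= 1")
  n <- max(length(successes), length(trials))
  successes <- rep_len(successes, n)
  trials <- rep_len(trials, n)
  if (any(successes < 0 | trials < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (any(successes > trials, na.rm = TRUE)) {
    stop("`successes` must not exceed `trials`")
  }
  rate <- pmin(pmax(successes / trials, eps), 1 - eps)
  out <- log2(rate / (1 - rate))
  out[trials < min_trials] <- NA_real_
  out
}

#' Read a long-format data table from a delimited file
#'
#' Expects a header `sample,group,feature,view,value`; empty fields or
#' `"NA"` mark unobserved entries.
#'
#' @param path File path (TSV by default).
#' @param sep Field separator.
#' @param likelihoods Passed on to [sgfa_data()].
#' @export
read_sgfa_long <- function(path, sep = "\t", likelihoods = NULL) {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  sgfa_data(tab, likelihoods = likelihoods)
}
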