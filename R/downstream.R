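#' Variance decomposition across factors, groups and views
#'
#' Computes the fraction of variance (coefficient of determination)
#' explained by each factor in every (group, view) block,
#' `R2 = 1 - SS_res / SS_tot`, where the per-factor residual uses the
#' rank-1 reconstruction from that factor alone and sums run over observed
#' entries of the (per-group centered) data.  `total` uses the full
#' K-factor reconstruction.  For Bernoulli/Poisson views the decomposition
#' is computed on the Gaussian pseudo-data implied by the final local
#' bounds.  Per-factor values are clipped below at zero for reporting; the
#' raw values are kept in `$raw`.  Per-factor values are not additive
#' across factors (factors need not be orthogonal).
#'
#' @param object A fitted `"sgfa"` model (must carry its data).
#' @return An object of class `sgfa_r2`: list with `r2` (K x G x M array,
#'   clipped), `raw`, and `total` (G x M matrix).
#' @export
variance_explained <- function(object) {
  stopifnot(inherits(object, "sgfa"))
  if (is.null(object$data) || is.null(object$data$blocks)) {
    stop("variance decomposition needs the training data; this model was loaded without it")
  }
  pp <- make_pp(object$data)
  state <- object$state
  K <- state$K
  mom <- all_moments(state)
  r2 <- array(NA_real_, c(K, pp$G, pp$M),
              dimnames = list(if (K) paste0("Factor", seq_len(K)),
                              pp$groups, pp$views))
  total <- matrix(NA_real_, pp$G, pp$M, dimnames = list(pp$groups, pp$views))
  for (g in seq_len(pp$G)) for (m in seq_len(pp$M)) {
    Msk <- pp$mask[[g]][[m]]
    Yt <- if (pp$lik[[m]] == "gaussian") pp$Y0[[g]][[m]] else get_TY(state, pp, g, m)$Yt
    sstot <- sum(Msk * Yt^2)
    if (sstot == 0) next  # all-zero observed block: R2 undefined
    EZ <- mom$z[[g]]$E
    EW <- mom$w[[m]]$E
    if (K) {
      full <- EZ %*% t(EW)
      total[g, m] <- 1 - sum(Msk * (Yt - full)^2) / sstot
      for (k in seq_len(K)) {
        resk <- Yt - tcrossprod(EZ[, k], EW[, k])
        r2[k, g, m] <- 1 - sum(Msk * resk^2) / sstot
      }
    } else {
      total[g, m] <- 0
    }
  }
  structure(list(r2 = pmax(r2, 0), raw = r2, total = total), class = "sgfa_r2")
}

#' @export
print.sgfa_r2 <- function(x, digits = 3, ...) {
  cat("Variance explained (fraction of total, per group x view)\n")
  cat("Totals (all factors jointly):\n")
  print(round(x$total, digits))
  if (dim(x$r2)[1L]) {
    cat("Per factor (max over blocks):\n")
    print(round(apply(x$r2, 1L, max, na.rm = TRUE), digits))
  }
  invisible(x)
}

#' Top weights of a factor in one view
#'
#' Features ranked by absolute weight, signed weights returned; the sign
#' indicates the direction of the effect (positive weight: higher levels
#' in samples with positive factor values).  Ties keep the original
#' feature order.
#'
#' @param object A fitted `"sgfa"` model.
#' @param view View name or index.
#' @param factor Factor index.
#' @param n Number of features (clamped to the view size).
#' @param scaled Scale weights to a maximum absolute value of 1.
#' @return `data.frame(feature, weight)` in decreasing `|weight|` order.
#' @export
top_weights <- function(object, view = 1, factor = 1, n = 10, scaled = FALSE) {
  stopifnot(inherits(object, "sgfa"), n >= 1)
  m <- resolve_view(object, view)
  if (factor < 1 || factor > object$K) {
    stop(sprintf("unknown factor %s (model has %d)", factor, object$K))
  }
  W <- object$state$W[[m]]
  w <- (W$g * W$mu)[, factor]
  if (scaled && max(abs(w)) > 0) w <- w / max(abs(w))
  ord <- order(-abs(w))  # stable: equal weights keep original order
  ord <- ord[seq_len(min(n, length(w)))]
  data.frame(feature = object$data$features[[m]][ord], weight = w[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

resolve_view <- function(object, view) {
  views <- object$data$views
  if (is.character(view)) {
    m <- match(view, views)
    if (is.na(m)) stop(sprintf("unknown view '%s'", view))
    return(m)
  }
  if (view < 1 || view > length(views)) stop("unknown view index ", view)
  as.integer(view)
}

#' Gene set enrichment of factor weights
#'
#' For every gene set, contrasts the weights of the foreground features
#' (set members present in the view) against the background (all other
#' features of the view) with a Welch two-sample t-test, by default on
#' absolute weights.  P-values are adjusted per factor across sets with
#' the Benjamini-Hochberg procedure; sets are flagged significant at an
#' FDR of 1% by default.
#'
#' @param object A fitted `"sgfa"` model.
#' @param gene_sets Named list of feature-identifier vectors (e.g. from
#'   [read_gmt()]).  Identifiers are matched case-sensitively.
#' @param view View name or index whose weights are tested.
#' @param factors Factor indices (default: all).
#' @param use_absolute Test absolute weights (default) or signed weights.
#' @param fdr Significance threshold on the adjusted p-value.
#' @return `data.frame(factor, set, size, t, p, p_adj, significant)`.
#' @export
run_enrichment <- function(object, gene_sets, view = 1, factors = NULL,
                           use_absolute = TRUE, fdr = 0.01) {
  stopifnot(inherits(object, "sgfa"), is.list(gene_sets))
  m <- resolve_view(object, view)
  if (is.null(factors)) factors <- seq_len(object$K)
  feats <- object$data$features[[m]]
  idx <- lapply(gene_sets, function(s) which(feats %in% s))
  small <- vapply(idx, length, 1L) < 2L
  if (any(small)) {
    warning("skipping gene sets with fewer than 2 matched features: ",
            paste(names(gene_sets)[small], collapse = ", "))
    idx <- idx[!small]
  }
  if (!length(idx)) stop("no gene set has >= 2 features in this view")
  W <- object$state$W[[m]]
  EW <- W$g * W$mu
  out <- list()
  for (k in factors) {
    w <- EW[, k]
    if (use_absolute) w <- abs(w)
    tt <- vapply(idx, function(i) {
      ht <- stats::t.test(w[i], w[-i])  # Welch by default
      c(ht$statistic, ht$p.value)
    }, numeric(2L))
    p_adj <- stats::p.adjust(tt[2L, ], method = "BH")
    out[[as.character(k)]] <- data.frame(
      factor = k, set = names(idx), size = vapply(idx, length, 1L),
      t = tt[1L, ], p = tt[2L, ], p_adj = p_adj,
      significant = p_adj < fdr,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers,
#' tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, "", 1L))
}

#' Factor scores with sample and group labels
#'
#' Posterior mean factor values, one row per sample, suitable for export
#' to external embedding or trajectory tools.
#'
#' @param object A fitted `"sgfa"` model.
#' @return `data.frame(sample, group, Factor1, ...)`.
#' @export
factor_scores <- function(object) {
  stopifnot(inherits(object, "sgfa"))
  out <- list()
  for (g in seq_along(object$data$groups)) {
    Z <- object$state$Z[[g]]
    EZ <- if (!is.null(Z$g)) Z$g * Z$mu else Z$mu
    colnames(EZ) <- if (object$K) paste0("Factor", seq_len(object$K))
    out[[g]] <- data.frame(sample = object$data$samples[[g]],
                           group = object$data$groups[g], EZ,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write factor scores to a tab-separated file
#'
#' @param object A fitted `"sgfa"` model.
#' @param path Output path.
#' @export
write_factors <- function(object, path) {
  utils::write.table(factor_scores(object), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
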