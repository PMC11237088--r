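#' Multiscale differential-abundance configuration
#'
#' @param kGrid neighborhood sizes for the multiscale score vector
#'   (default \code{seq(100, 4000, 500)}; the reduced preset
#'   \code{seq(100, 1000, 100)} suits large data sets).  Every k must be
#'   below the cell count.
#' @param thresholds lower/upper DA-measure thresholds (default
#'   \code{c(-0.8, 0.8)}; alternate preset \code{c(-0.5, 0.5)}).
#' @param nPcs embedding dimensionality used upstream (default 40).
#' @param clusterResolution Louvain resolution for DA-cell clustering
#'   (default 0.01).
#' @param lambda ridge penalty of the logistic DA-measure model; kept
#'   small (default 1e-4) so it stabilizes the fit numerically without
#'   shrinking predictions away from the local condition composition.
#' @param seed integer seed for the stochastic steps.
#' @return a list of class \code{DaConfig}.
#' @export
daConfig <- function(kGrid = seq(100, 4000, by = 500),
                     thresholds = c(-0.8, 0.8), nPcs = 40,
                     clusterResolution = 0.01, lambda = 1e-4, seed = 1) {
  if (any(thresholds <= -1 | thresholds >= 1) ||
      thresholds[1] >= thresholds[2])
    stop("thresholds must satisfy -1 < lower < upper < 1")
  structure(list(kGrid = as.integer(kGrid), thresholds = thresholds,
                 nPcs = as.integer(nPcs),
                 clusterResolution = clusterResolution,
                 lambda = lambda, seed = as.integer(seed)),
            class = "DaConfig")
}

#' PCA embedding of normalized cells
#'
#' Top principal components of the cell-by-gene log-normalized matrix,
#' the embedding consumed by the DA stage (integration of the full
#' cohort is assumed to have happened upstream in real data).
#'
#' @param cells a normalized \code{SingleCellExperiment}.
#' @param nPcs number of components (default 40, capped by the data).
#' @return numeric matrix, cells x PCs.
#' @export
daEmbedding <- function(cells, nPcs = 40) {
  x <- t(SummarizedExperiment::assay(cells, "lognorm"))
  keep <- apply(x, 2, stats::sd) > 0
  pr <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  k <- min(nPcs, ncol(pr$x))
  pr$x[, seq_len(k), drop = FALSE]
}

#' Multiscale kNN condition-composition score vectors
#'
#' For each cell and each neighborhood size k, the score is the fraction
#' of the cell's k nearest Euclidean neighbors (excluding itself, ties in
#' distance broken by cell index) that carry condition A, where A is the
#' first level of \code{condition}.  Scores are invariant to rigid
#' rotation of the embedding.
#'
#' @param embedding numeric matrix, cells x dimensions; finite.
#' @param condition per-cell two-level label; the first sorted unique
#'   value (or first factor level) is condition A.
#' @param kGrid neighborhood sizes; every value must be < number of
#'   cells.
#' @return numeric matrix, cells x length(kGrid), entries in [0, 1].
#' @export
knnScoreVector <- function(embedding, condition,
                           kGrid = seq(100, 4000, by = 500)) {
  n <- nrow(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  if (any(kGrid >= n)) stop("every k must be < the number of cells")
  lev <- if (is.factor(condition)) levels(condition) else
    sort(unique(as.character(condition)))
  if (length(lev) != 2) stop("condition must have exactly two levels")
  isA <- as.character(condition) == lev[1]
  if (!any(isA) || all(isA)) stop("both conditions must be present")
  # full pairwise squared distances via the Gram-matrix identity
  sq <- rowSums(embedding^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(embedding)
  maxK <- max(kGrid)
  scores <- matrix(NA_real_, n, length(kGrid))
  for (i in seq_len(n)) {
    d <- D2[i, ]
    d[i] <- Inf  # exclude self
    ord <- order(d, seq_len(n))[seq_len(maxK)]
    cum <- cumsum(isA[ord])
    scores[i, ] <- cum[kGrid] / kGrid
  }
  dimnames(scores) <- list(rownames(embedding), paste0("k", kGrid))
  scores
}

#' DA measure from multiscale scores
#'
#' An L2-regularized logistic model predicts the condition label from the
#' multiscale score vector; the DA measure is \code{2 * qhat - 1} where
#' \code{qhat} is the predicted probability of condition A, so the
#' measure lies in [-1, 1], is near 0 for cells in mixed neighborhoods
#' and approaches +1 (-1) for cells embedded in condition-A
#' (condition-B) enriched territory.  Swapping the condition labels
#' negates the measure up to fitting tolerance.
#'
#' @param scores cells x k score matrix from
#'   \code{\link{knnScoreVector}}.
#' @param condition the same per-cell label the scores were computed
#'   with.
#' @param lambda ridge penalty (default 1e-4; see
#'   \code{\link{daConfig}}).
#' @return numeric per-cell measure in [-1, 1].
#' @export
daMeasure <- function(scores, condition, lambda = 1e-4) {
  lev <- if (is.factor(condition)) levels(condition) else
    sort(unique(as.character(condition)))
  if (length(lev) != 2) stop("condition must have exactly two levels")
  y <- as.integer(as.character(condition) == lev[1])
  if (all(y == y[1])) stop("single-condition input")
  fit <- glmnet::glmnet(scores, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  qhat <- as.numeric(stats::predict(fit, newx = scores,
                                    type = "response"))
  2 * qhat - 1
}

#' Select DA cells by measure thresholds
#'
#' @param measures per-cell DA measure.
#' @param thresholds lower/upper cutoffs (default \code{c(-0.8, 0.8)}).
#' @return data.frame \code{cell} (index), \code{measure},
#'   \code{direction} (\code{"A"} for measure >= upper, \code{"B"} for
#'   <= lower).  Zero rows when nothing passes.
#' @export
selectDaCells <- function(measures, thresholds = c(-0.8, 0.8)) {
  up <- which(measures >= thresholds[2])
  dn <- which(measures <= thresholds[1])
  data.frame(cell = c(up, dn),
             measure = measures[c(up, dn)],
             direction = rep(c("A", "B"), c(length(up), length(dn))),
             stringsAsFactors = FALSE)
}

#' Cluster DA cells into subpopulations
#'
#' Louvain community detection on a k-nearest-neighbor graph (k = 20 by
#' default) of the DA cells at the given resolution; singleton
#' communities are merged into the nearest community by centroid
#' distance.  Labels are deterministic given the seed.
#'
#' @param embedding embedding rows restricted to the selected DA cells.
#' @param resolution Louvain resolution (default 0.01).
#' @param k graph neighborhood size (default 20, capped by the cell
#'   count).
#' @param seed integer seed.
#' @return integer cluster labels (all 1 when fewer than 2 cells).
#' @export
clusterDaCells <- function(embedding, resolution = 0.01, k = 20,
                           seed = 1) {
  n <- nrow(embedding)
  if (n < 2) return(rep(1L, n))
  k <- min(k, n - 1)
  sq <- rowSums(embedding^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(embedding)
  edges <- integer(0)
  for (i in seq_len(n)) {
    d <- D2[i, ]; d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  gr <- igraph::simplify(igraph::make_graph(edges, n = n,
                                            directed = FALSE))
  memb <- withSeed(seed,
    igraph::membership(igraph::cluster_louvain(gr,
                                               resolution = resolution)))
  memb <- as.integer(memb)
  # merge singleton communities into the nearest community by centroid
  repeat {
    tab <- table(memb)
    singles <- as.integer(names(tab)[tab == 1])
    if (!length(singles) || length(tab) == 1) break
    for (s in singles) {
      i <- which(memb == s)
      cents <- vapply(setdiff(unique(memb), s), function(cl)
        sum((colMeans(embedding[memb == cl, , drop = FALSE]) -
               embedding[i, ])^2), 0)
      memb[i] <- setdiff(unique(memb), s)[which.min(cents)]
    }
  }
  as.integer(factor(memb))
}

#' Run the full DA detection chain
#'
#' \code{\link{knnScoreVector}} -> \code{\link{daMeasure}} ->
#' \code{\link{selectDaCells}} -> \code{\link{clusterDaCells}} on one
#' embedding.  Clustering is skipped gracefully when no cell passes the
#' thresholds.
#'
#' @param embedding cells x PCs matrix.
#' @param condition per-cell two-level label.
#' @param config a \code{\link{daConfig}}; k values at or above the cell
#'   count are an error.
#' @return list: \code{scores}, \code{measure}, \code{selected} (from
#'   \code{selectDaCells}, with a \code{subpopulation} column added),
#'   \code{config}.
#' @export
daRun <- function(embedding, condition, config = daConfig()) {
  scores <- knnScoreVector(embedding, condition, config$kGrid)
  measure <- daMeasure(scores, condition, lambda = config$lambda)
  sel <- selectDaCells(measure, config$thresholds)
  if (nrow(sel)) {
    sel$subpopulation <- clusterDaCells(
      embedding[sel$cell, , drop = FALSE],
      resolution = config$clusterResolution, seed = config$seed)
  } else {
    sel$subpopulation <- integer(0)
  }
  list(scores = scores, measure = measure, selected = sel,
       config = config)
}
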