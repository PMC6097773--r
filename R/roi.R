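#' Edge-weighted mesh graph of a source space
#'
#' igraph object with one vertex per mesh vertex and one edge per unique
#' triangle edge, weighted by Euclidean edge length (used for geodesic
#' distances).
#'
#' @param sources a `source_space`
#' @return an igraph graph with a `weight` edge attribute
#' @export
mesh_graph <- function(sources) {
  tri <- sources$triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  ed <- unique(ed)
  w <- sqrt(rowSums((sources$positions[ed[, 1], ] -
                     sources$positions[ed[, 2], ])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic (shortest-path) distances on the source mesh
#'
#' @param sources a `source_space`
#' @param from vertex indices (rows of the result)
#' @param to vertex indices (columns; default all)
#' @param graph optional precomputed [mesh_graph()]
#' @return matrix of geodesic distances in mm
#' @export
geodesic_distances <- function(sources, from, to = NULL, graph = NULL) {
  if (is.null(graph)) graph <- mesh_graph(sources)
  if (is.null(to)) to <- seq_len(sources$n_vertices)
  igraph::distances(graph, v = from, to = to,
                    weights = igraph::E(graph)$weight)
}

#' Define regions of interest by geodesic growth from seed vertices
#'
#' Each ROI is grown from its seed by taking the `target_size` mesh vertices
#' with smallest geodesic distance to the seed (ties broken by lowest vertex
#' index), mimicking surface patches of roughly equal area around the
#' ground-truth dipoles.
#'
#' @param sources a `source_space`
#' @param seeds integer vector of seed vertex indices (optionally named)
#' @param target_size number of member vertices per ROI (default 45,
#'   i.e. within the conventional 40-50 vertex patch size)
#' @param graph optional precomputed [mesh_graph()]
#' @return list of `roi_def` objects: `seed`, `members` (sorted by geodesic
#'   distance), `geodesic_mm` of each member
#' @export
define_rois <- function(sources, seeds, target_size = 45, graph = NULL) {
  stopifnot(all(seeds >= 1), all(seeds <= sources$n_vertices),
            target_size >= 1)
  if (is.null(graph)) graph <- mesh_graph(sources)
  d <- geodesic_distances(sources, from = seeds, graph = graph)
  if (any(!is.finite(d[, 1]))) stop("mesh is disconnected at a seed")
  out <- lapply(seq_along(seeds), function(i) {
    ord <- order(d[i, ], seq_len(ncol(d)))[seq_len(target_size)]
    structure(list(seed = seeds[i], members = ord,
                   geodesic_mm = d[i, ord]),
              class = "roi_def")
  })
  names(out) <- names(seeds)
  out
}

#' Dominant-direction sign map of an ROI
#'
#' The dominant direction is the first principal direction of the member
#' normals (eigenvector of their outer-product sum), with its sign fixed so
#' that the majority of member normals have a positive scalar product with
#' it. Members whose normal points against the dominant direction receive
#' sign -1; applied to the extracted time series this aligns the
#' minimum-norm polarity across a patch.
#'
#' @param sources a `source_space`
#' @param roi a `roi_def`
#' @return numeric vector of +1/-1 per ROI member; dominant direction
#'   attached as attribute `"direction"`
#' @export
dominant_sign_flip <- function(sources, roi) {
  Nrm <- sources$normals[roi$members, , drop = FALSE]
  pc <- eigen(crossprod(Nrm), symmetric = TRUE)$vectors[, 1]
  dots <- as.numeric(Nrm %*% pc)
  if (sum(dots > 0) < sum(dots < 0)) pc <- -pc
  s <- sign(as.numeric(Nrm %*% pc))
  s[s == 0] <- 1
  attr(s, "direction") <- pc
  s
}

#' Select a representative dipole within an ROI
#'
#' Strategies: `GT1` takes the ground-truth (seed) vertex; `GT2` the member
#' with highest Pearson correlation to the ground-truth series; `DD1` the
#' member most correlated with the ROI-average series; `DD2` the member with
#' highest power (mean squared amplitude); `DD3` the member with the
#' largest-magnitude entry of the first left singular vector of the
#' member-by-time matrix (the dipole best aligned with the dominant
#' variability); `DD4` the member whose resolution index (diagonal of the
#' resolution matrix) is closest to 1; `DD5` the member with the highest
#' cross-talk index, the ratio of mean outflow CTF (sum of its resolution
#' column) to mean inflow CTF (sum of its resolution row). Data-driven
#' scores are computed on trial-averaged, sign-flipped member series; ties
#' are broken by lowest vertex index.
#'
#' @param strategy one of `"GT1","GT2","DD1","DD2","DD3","DD4","DD5"`
#' @param roi a `roi_def`
#' @param estimates a `trial_tensor` whose channels are the ROI members (in
#'   `roi$members` order), e.g. from [apply_kernel()] with `rows =
#'   roi$members`
#' @param signs sign-flip vector from [dominant_sign_flip()] (default all +1)
#' @param aux list of auxiliary inputs: `gt_series` (ground-truth series,
#'   required by GT2), `resolution` (full resolution matrix, required by
#'   DD4/DD5)
#' @return object of class `selection_result`: `strategy`, `vertex` (mesh
#'   index), `member` (position within the ROI), `sign`, `series` (selected
#'   sign-flipped series, trials x samples) and `mean_series`
#' @export
select_dipole <- function(strategy, roi, estimates, signs = NULL,
                          aux = list()) {
  strategy <- match.arg(strategy,
                        c("GT1", "GT2", "DD1", "DD2", "DD3", "DD4", "DD5"))
  stopifnot(inherits(estimates, "trial_tensor"))
  d <- dim(estimates$data)
  nm <- length(roi$members)
  stopifnot(d[2] == nm)
  if (is.null(signs)) signs <- rep(1, nm)

  # trial-averaged, sign-flipped member series (members x samples)
  avg <- colMeans(estimates$data) * signs

  member <- switch(strategy,
    GT1 = match(roi$seed, roi$members),
    GT2 = {
      if (is.null(aux$gt_series)) stop("GT2 requires aux$gt_series")
      which.max(apply(avg, 1, function(z) safe_cor(z, aux$gt_series)))
    },
    DD1 = {
      roi_mean <- colMeans(avg)
      which.max(apply(avg, 1, function(z) safe_cor(z, roi_mean)))
    },
    DD2 = which.max(rowMeans(avg^2)),
    DD3 = {
      sv <- svd(avg, nu = 1, nv = 0)
      which.max(abs(sv$u[, 1]))
    },
    DD4 = {
      if (is.null(aux$resolution)) stop("DD4 requires aux$resolution")
      ridx <- diag(aux$resolution)[roi$members]
      which.min(abs(ridx - 1))
    },
    DD5 = {
      if (is.null(aux$resolution)) stop("DD5 requires aux$resolution")
      outflow <- colSums(aux$resolution[, roi$members, drop = FALSE])
      inflow <- rowSums(aux$resolution[roi$members, , drop = FALSE])
      which.max(outflow / inflow)
    })
  if (strategy == "GT1" && is.na(member)) stop("seed is not an ROI member")

  series <- estimates$data[, member, , drop = FALSE] * signs[member]
  dim(series) <- c(d[1], d[3])
  structure(list(strategy = strategy, vertex = roi$members[member],
                 member = member, sign = signs[member],
                 series = series, mean_series = avg[member, ]),
            class = "selection_result")
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  cor(a, b)
}

#' Score a dipole selection against the ground truth
#'
#' Euclidean and geodesic distance between the selected vertex and the
#' ground-truth vertex, Pearson correlation between the trial-averaged
#' selected series and the ground-truth series, and the mean squared error
#' after a least-squares affine fit (gain + offset) of the selected series
#' to the ground truth — the affine fit absorbs the strong amplitude
#' attenuation of minimum-norm estimates so that only the shape is scored.
#'
#' @param result a `selection_result`
#' @param gt_vertex ground-truth vertex index
#' @param gt_series ground-truth (trial-averaged) time series
#' @param sources a `source_space`
#' @param graph optional precomputed [mesh_graph()]
#' @return object of class `selection_metrics`: list with `euclidean_mm`,
#'   `geodesic_mm`, `pearson_r`, `mse_linear_fit`
#' @export
score_selection <- function(result, gt_vertex, gt_series, sources,
                            graph = NULL) {
  sel <- result$vertex
  eu <- sqrt(sum((sources$positions[sel, ] - sources$positions[gt_vertex, ])^2))
  ge <- as.numeric(geodesic_distances(sources, from = sel, to = gt_vertex,
                                      graph = graph))
  x <- result$mean_series
  if (sd(x) == 0 || sd(gt_series) == 0) {
    r <- NA_real_
    mse <- mean((gt_series - mean(gt_series))^2)
  } else {
    r <- cor(x, gt_series)
    fit <- lm(gt_series ~ x)
    mse <- mean(resid(fit)^2)
  }
  structure(list(euclidean_mm = eu, geodesic_mm = ge,
                 pearson_r = r, mse_linear_fit = mse),
            class = "selection_metrics")
}
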