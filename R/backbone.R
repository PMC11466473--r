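# Metric backbone extraction: convert confidence scores to distances and
# keep exactly the edges whose direct distance equals the shortest-path
# distance between their endpoints. Semi-metric edges — those strictly
# longer than some indirect path — are redundant for all shortest paths.

#' Convert a confidence score to a distance
#'
#' The default transform is the nonlinear isomorphism `d = 1/s - 1`,
#' mapping score 1 to distance 0 and strictly decreasing in `s`, the usual
#' choice in the metric-backbone literature for proximity weights in
#' (0, 1]. `"neglog"` (`-log s`) and `"oneminus"` (`1 - s`) are available
#' for sensitivity analyses; the backbone depends on the transform because
#' path lengths add.
#'
#' @param score numeric in (0, 1].
#' @param transform one of `"inverse"` (default), `"neglog"`, `"oneminus"`.
#' @return non-negative distances, same length as `score`.
#' @examples
#' toDistance(c(1, 0.5, 0.25))   # 0, 1, 3
#' @export
toDistance <- function(score, transform = c("inverse", "neglog", "oneminus")) {
  transform <- match.arg(transform)
  if (!is.numeric(score) || any(!is.finite(score)) ||
      any(score <= 0) || any(score > 1))
    stop("scores must lie in (0, 1]")
  switch(transform,
         inverse = 1 / score - 1,
         neglog = -log(score),
         oneminus = 1 - score)
}

#' Extract the metric backbone of a layer
#'
#' Classifies every edge as metric or semi-metric and returns the backbone:
#' all nodes plus exactly the metric edges. An edge `(u, v)` with direct
#' distance `d_uv` is metric iff `d_uv` does not exceed the shortest
#' indirect `u`-`v` path by more than the relative tolerance — equivalently
#' iff `d_uv` equals the all-pairs shortest-path distance. An indirect path
#' exactly equal to the direct distance counts the edge as metric, so the
#' backbone realizes at least one shortest path per pair and the operation
#' is idempotent. The backbone preserves all shortest-path distances of the
#' layer ([verifyDistancePreservation()]).
#'
#' Distances are compared with shortest paths computed by Dijkstra from
#' every node (via [igraph::distances()]).
#'
#' @param layer a [Layer-class] with finite non-negative edge distances.
#' @param relTol relative tolerance for float comparison; default 1e-9.
#' @return a [BackboneResult-class].
#' @export
metricBackbone <- function(layer, relTol = 1e-9) {
  stopifnot(is(layer, "Layer"))
  g <- layer@graph
  d <- igraph::edge_attr(g, "distance")
  if (igraph::ecount(g) > 0 && (any(!is.finite(d)) || any(d < 0)))
    stop("edge distances must be finite and non-negative")
  if (igraph::ecount(g) == 0) {
    return(new("BackboneResult", layer = layer, metric = logical(0),
               backbone = g))
  }
  sp <- igraph::distances(g, weights = d, algorithm = "dijkstra")
  el <- igraph::as_edgelist(g, names = FALSE)
  spDirect <- sp[cbind(el[, 1], el[, 2])]
  # sp <= d always; the edge is semi-metric iff a strictly shorter
  # (necessarily indirect) path exists
  metric <- spDirect >= d / (1 + relTol)
  bb <- igraph::delete_edges(g, which(!metric))
  new("BackboneResult", layer = layer, metric = metric, backbone = bb)
}

#' Check that a backbone preserves all shortest-path distances
#'
#' Recomputes all-pairs shortest-path distances on the backbone and on the
#' original layer and reports whether they agree within the relative
#' tolerance, together with the maximum relative deviation observed
#' (deviations on zero-distance pairs are measured absolutely).
#'
#' @param bb a [BackboneResult-class].
#' @param relTol relative tolerance; default 1e-9.
#' @return list with `ok` (logical) and `maxDeviation` (numeric).
#' @export
verifyDistancePreservation <- function(bb, relTol = 1e-9) {
  stopifnot(is(bb, "BackboneResult"))
  g <- bb@layer@graph
  if (igraph::vcount(g) == 0) return(list(ok = TRUE, maxDeviation = 0))
  dOrig <- igraph::distances(g, weights = igraph::edge_attr(g, "distance"),
                             algorithm = "dijkstra")
  wBb <- igraph::edge_attr(bb@backbone, "distance")
  if (is.null(wBb)) wBb <- numeric(0)
  dBb <- igraph::distances(bb@backbone, weights = wBb,
                           algorithm = "dijkstra")
  finite <- is.finite(dOrig)
  if (any(is.finite(dBb) != finite))
    return(list(ok = FALSE, maxDeviation = Inf))
  dev <- abs(dBb[finite] - dOrig[finite]) / pmax(dOrig[finite], 1)
  maxDev <- if (length(dev)) max(dev) else 0
  list(ok = maxDev <= relTol, maxDeviation = maxDev)
}

#' Backbone of the backbone subgraph as a Layer
#'
#' Convenience: wrap a backbone's subgraph as a [Layer-class] so it can be
#' fed back into [metricBackbone()] (idempotence) or into node-feature
#' computations.
#'
#' @param bb a [BackboneResult-class].
#' @return a [Layer-class] whose graph is the backbone.
#' @export
backboneAsLayer <- function(bb) {
  stopifnot(is(bb, "BackboneResult"))
  .layerFromGraph(bb@backbone, bb@layer@species)
}
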