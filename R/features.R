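# Node-connectivity features, conserved-vs-non-conserved comparisons, a
# uniform edge-rewiring null, and cross-validated conservation
# classifiers.

#' Node connectivity features of a layer
#'
#' Degree centrality (`degree / (n - 1)`) and PageRank (damped random-walk
#' stationary probability, unweighted topology) per node, plus the node's
#' conservation label when present.
#'
#' @param layer a non-empty [Layer-class].
#' @param damping PageRank damping factor; default 0.85.
#' @return data.frame `gene`, `degree_centrality`, `page_rank`,
#'   `conserved`.
#' @export
nodeFeatures <- function(layer, damping = 0.85) {
  stopifnot(is(layer, "Layer"))
  g <- layer@graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph: no node features")
  dc <- if (n > 1) igraph::degree(g) / (n - 1) else rep(0, n)
  pr <- igraph::page_rank(g, damping = damping, weights = NA)$vector
  flags <- igraph::vertex_attr(g, "conserved")
  if (is.null(flags)) flags <- rep(NA, n)
  data.frame(gene = igraph::V(g)$name,
             degree_centrality = unname(dc),
             page_rank = unname(pr),
             conserved = as.logical(flags),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test (asymptotic p-value), e.g. for comparing
#' degree-centrality distributions of conserved vs non-conserved genes.
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @return list with `D` (statistic) and `p.value`.
#' @export
ksCompare <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be non-empty")
  res <- suppressWarnings(ks.test(valuesA, valuesB,
                                  alternative = "two.sided", exact = FALSE))
  list(D = unname(res$statistic), p.value = res$p.value)
}

#' Randomly rewire a fraction of a layer's edges
#'
#' Deletes `ceiling(fraction * |E|)` randomly chosen edges and replaces
#' them one by one with edges between uniformly random node pairs,
#' rejecting self-loops and duplicates, so node set, edge count and the
#' simple-graph property are preserved and the removed edges' scores are
#' carried over to the replacements. This dilutes any structure attached
#' to node identity (it is deliberately not degree-preserving). The result
#' is deterministic given `seed`.
#'
#' @param layer a [Layer-class].
#' @param fraction fraction of edges to rewire, in `[0, 1]`.
#' @param seed integer seed.
#' @return a rewired [Layer-class].
#' @export
rewireLayer <- function(layer, fraction, seed) {
  stopifnot(is(layer, "Layer"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  g <- layer@graph
  m <- igraph::ecount(g)
  nRewire <- ceiling(fraction * m)
  if (nRewire == 0) return(layer)
  set.seed(seed)
  doomed <- sample.int(m, nRewire)
  scores <- igraph::edge_attr(g, "score")[doomed]
  dists <- igraph::edge_attr(g, "distance")[doomed]
  keepIdx <- setdiff(seq_len(m), doomed)
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (i in keepIdx)
    assign(paste(min(el[i, ]), max(el[i, ])), TRUE, envir = have)
  newEdges <- matrix(0L, nrow = nRewire, ncol = 2)
  for (k in seq_len(nRewire)) {
    repeat {
      uv <- sample.int(n, 2, replace = TRUE)
      if (uv[1] == uv[2]) next
      key <- paste(min(uv), max(uv))
      if (!exists(key, envir = have, inherits = FALSE)) {
        assign(key, TRUE, envir = have)
        newEdges[k, ] <- uv
        break
      }
    }
  }
  g2 <- igraph::delete_edges(g, doomed)
  g2 <- igraph::add_edges(g2, t(newEdges),
                          attr = list(score = scores, distance = dists))
  .layerFromGraph(g2, layer@species)
}

# rank-based AUC of scores against binary labels (ties handled by
# midranks); equivalent to the Mann-Whitney statistic scaled to [0, 1]
.rankAuc <- function(scores, labels) {
  r <- rank(scores)
  nPos <- sum(labels); nNeg <- sum(!labels)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classify node conservation from network features
#'
#' Stratified k-fold cross-validation of a random forest (100 trees) or a
#' linear support-vector machine (cost 1, features standardized on each
#' training fold) predicting the conserved label from connectivity
#' features. Reports per-fold and mean ROC AUC plus pooled out-of-fold
#' precision-recall curve points. Deterministic given `seed`.
#'
#' @param ft feature table from [nodeFeatures()] (or any data.frame with a
#'   logical `conserved` column); feature columns default to
#'   `degree_centrality` and `page_rank`.
#' @param model `"random-forest"` or `"linear-svm"`.
#' @param folds number of CV folds; default 4.
#' @param seed integer seed driving fold assignment and model fitting.
#' @param features character vector of feature column names.
#' @return list with `model`, `folds`, `seed`, `fold_assignment`,
#'   `auc_per_fold`, `mean_auc`, `pr_curve` (data.frame `recall`,
#'   `precision`), and `hyperparameters`.
#' @export
classifyConservation <- function(ft, model = c("random-forest", "linear-svm"),
                                 folds = 4, seed = 1,
                                 features = c("degree_centrality",
                                              "page_rank")) {
  model <- match.arg(model)
  stopifnot(all(features %in% colnames(ft)), "conserved" %in% colnames(ft))
  y <- as.logical(ft$conserved)
  if (any(is.na(y))) stop("conserved labels contain NA")
  if (length(unique(y)) < 2)
    stop("both classes must be present to cross-validate")
  x <- as.matrix(ft[, features, drop = FALSE])
  if (any(!is.finite(x))) stop("features must be finite")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  scores <- numeric(length(y))
  aucPerFold <- numeric(folds)
  for (k in seq_len(folds)) {
    test <- fold == k
    xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
    xte <- x[test, , drop = FALSE]
    if (model == "random-forest") {
      fit <- randomForest::randomForest(
        x = xtr, y = factor(ytr, levels = c(FALSE, TRUE)), ntree = 100)
      sc <- predict(fit, xte, type = "prob")[, "TRUE"]
    } else {
      fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(FALSE, TRUE)),
                        kernel = "linear", cost = 1, scale = TRUE)
      dv <- attr(predict(fit, xte, decision.values = TRUE),
                 "decision.values")[, 1]
      # orient decision values so larger means more likely conserved
      dvTr <- attr(predict(fit, xtr, decision.values = TRUE),
                   "decision.values")[, 1]
      if (.rankAuc(dvTr, ytr) < 0.5) dv <- -dv
      sc <- dv
    }
    scores[test] <- sc
    aucPerFold[k] <- as.numeric(pROC::auc(
      response = y[test], predictor = sc, quiet = TRUE,
      levels = c(FALSE, TRUE), direction = "<"))
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord])
  precision <- tp / seq_along(tp)
  recall <- tp / sum(y)
  pr <- data.frame(recall = recall, precision = precision)
  list(model = model, folds = folds, seed = seed, fold_assignment = fold,
       auc_per_fold = aucPerFold, mean_auc = mean(aucPerFold),
       pr_curve = pr,
       hyperparameters = if (model == "random-forest")
         list(ntree = 100) else list(kernel = "linear", cost = 1,
                                     scale = TRUE))
}
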