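#' Regression random forest with OOB permutation importance
#'
#' A classical Breiman regression forest: bootstrap samples, CART trees
#' with \code{mtry = ceiling(m/3)} candidate features per split and
#' minimum node size 5, out-of-bag (OOB) mean-squared error, and
#' permutation importance (mean OOB increase in MSE when a feature is
#' permuted). The pseudo-R-squared is 1 - MSE_oob / Var(y) (population
#' variance). Implemented in compiled code; fully deterministic under
#' \code{seed}.
#'
#' @param X numeric matrix, samples x features (column names kept as
#'   feature ids).
#' @param y numeric response.
#' @param ntree number of trees.
#' @param mtry candidate features per split; default \code{ceiling(m/3)}.
#' @param min_node minimum node size to attempt a split, default 5.
#' @param seed integer seed.
#' @return list: importance (named), oob_mse, pseudo_r2, oob_pred.
#' @export
rfRegression <- function(X, y, ntree = 10000L, mtry = NULL,
                         min_node = 5L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L, ncol(X) >= 1L)
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 3))
  res <- .rf_regression_cpp(X, as.numeric(y), as.integer(ntree),
                            as.integer(mtry), as.integer(min_node),
                            as.integer(seed))
  names(res$importance) <- colnames(X)
  res
}

#' Triplicate random forests with a convergence check
#'
#' Runs three forests from distinct seed substreams, computes all
#' pairwise Pearson correlations between their importance vectors and,
#' if the minimum correlation is below \code{convergence_r}, reruns all
#' three at \code{ntree_escalated}. A run still unconverged after
#' escalation proceeds with a warning (no further escalation).
#'
#' @param X residualized genotype matrix (samples x markers, complete).
#' @param y residualized phenotype.
#' @param ntree_initial,ntree_escalated tree counts, defaults 10,000 /
#'   100,000.
#' @param convergence_r minimum pairwise importance correlation, 0.90.
#' @param seed integer master seed for the three substreams.
#' @return list of class \code{"ImportanceRun"}: importance (markers x 3
#'   matrix), mean_importance, pairwise_r (length-3), converged, n_trees,
#'   escalated, pseudo_r2 (length-3), mean_pseudo_r2.
#' @export
rfImportanceConverged <- function(X, y, ntree_initial = 10000L,
                                  ntree_escalated = 100000L,
                                  convergence_r = 0.90, seed = 1L) {
  stopifnot(nrow(as.matrix(X)) >= 10L)
  runAt <- function(ntree) {
    runs <- lapply(1:3, function(k)
      rfRegression(X, y, ntree = ntree,
                   seed = stageSeed(seed, paste0("rf-rep", k))))
    imp <- vapply(runs, function(r) r$importance,
                  numeric(ncol(as.matrix(X))))
    r2 <- vapply(runs, function(r) r$pseudo_r2, 0)
    prs <- c(cor(imp[, 1], imp[, 2]), cor(imp[, 1], imp[, 3]),
             cor(imp[, 2], imp[, 3]))
    prs[!is.finite(prs)] <- 0
    list(importance = imp, pairwise_r = prs, pseudo_r2 = r2,
         n_trees = ntree)
  }
  res <- runAt(ntree_initial)
  escalated <- FALSE
  if (min(res$pairwise_r) < convergence_r &&
      ntree_escalated > ntree_initial) {
    escalated <- TRUE
    res <- runAt(ntree_escalated)
  }
  converged <- min(res$pairwise_r) >= convergence_r
  if (!converged)
    warning("importance correlations below ", convergence_r,
            " after escalation; proceeding")
  structure(list(importance = res$importance,
                 mean_importance = rowMeans(res$importance),
                 pairwise_r = res$pairwise_r, converged = converged,
                 n_trees = res$n_trees, escalated = escalated,
                 pseudo_r2 = res$pseudo_r2,
                 mean_pseudo_r2 = mean(res$pseudo_r2)),
            class = "ImportanceRun")
}

#' @export
print.ImportanceRun <- function(x, ...) {
  cat(sprintf(
    "triplicate RF (%d trees%s): min pairwise r = %.3f (%sconverged), mean pseudo-R2 = %.3f\n",
    x$n_trees, if (x$escalated) ", escalated" else "",
    min(x$pairwise_r), if (x$converged) "" else "NOT ", x$mean_pseudo_r2))
  invisible(x)
}

#' Union of the per-replicate top importance fractions
#'
#' From each of the three replicate forests, take the top
#' \code{ceiling(top_fraction * m)} markers by importance; return the
#' union (at most three times that count).
#'
#' @param run an \code{"ImportanceRun"}.
#' @param top_fraction fraction of markers per replicate, default 0.02.
#' @return character vector of marker ids.
#' @export
selectTopUnion <- function(run, top_fraction = 0.02) {
  imp <- run$importance
  m <- nrow(imp)
  k <- min(m, max(1L, ceiling(top_fraction * m)))
  ids <- rownames(imp)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  sel <- unique(unlist(lapply(1:3, function(r)
    ids[order(imp[, r], decreasing = TRUE)[seq_len(k)]])))
  sort(sel)
}

#' Backward purging of a marker subset by random-forest importance
#'
#' Starting from the selected subset, repeatedly runs triplicate forests
#' (with the convergence rule), records the mean pseudo-R-squared, and
#' removes the single marker with the lowest mean importance (ties broken
#' lexicographically by marker id) until two markers remain. The best
#' subset is the one maximizing mean pseudo-R-squared (earliest such step
#' on ties).
#'
#' @param X residualized genotype matrix restricted to the starting
#'   subset (samples x markers, >= 3 markers).
#' @param y residualized phenotype.
#' @param ntree_initial,ntree_escalated,convergence_r as in
#'   [rfImportanceConverged()].
#' @param seed integer master seed; each step uses its own substream.
#' @return list of class \code{"PurgeTrace"}: \code{steps} (data.frame:
#'   step, n_markers, mean_pseudo_r2, converged, removed), \code{sets}
#'   (list of marker-id vectors per step), \code{best_step},
#'   \code{best_markers}, \code{best_pseudo_r2}.
#' @export
backwardPurge <- function(X, y, ntree_initial = 10000L,
                          ntree_escalated = 100000L,
                          convergence_r = 0.90, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("starting subset must have at least 3 markers")
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  cur <- sort(colnames(X))
  steps <- list(); sets <- list(); step <- 0L
  while (length(cur) >= 2L) {
    step <- step + 1L
    run <- suppressWarnings(rfImportanceConverged(
      X[, cur, drop = FALSE], y, ntree_initial, ntree_escalated,
      convergence_r, seed = stageSeed(seed, paste0("purge-step", step))))
    removed <- NA_character_
    if (length(cur) > 2L) {
      mi <- run$mean_importance
      removed <- cur[order(mi, cur)][1]   # lowest importance, lexical tie
    }
    steps[[step]] <- data.frame(step = step, n_markers = length(cur),
                                mean_pseudo_r2 = run$mean_pseudo_r2,
                                converged = run$converged,
                                removed = removed)
    sets[[step]] <- cur
    if (length(cur) == 2L) break
    cur <- setdiff(cur, removed)
  }
  tab <- do.call(rbind, steps)
  best <- which.max(tab$mean_pseudo_r2)   # earliest max on ties
  structure(list(steps = tab, sets = sets, best_step = best,
                 best_markers = sets[[best]],
                 best_pseudo_r2 = tab$mean_pseudo_r2[best]),
            class = "PurgeTrace")
}

#' @export
print.PurgeTrace <- function(x, ...) {
  cat(sprintf(
    "backward purge: %d steps (%d -> 2 markers); best step %d with %d markers, pseudo-R2 = %.3f\n",
    nrow(x$steps), x$steps$n_markers[1], x$best_step,
    length(x$best_markers), x$best_pseudo_r2))
  invisible(x)
}
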