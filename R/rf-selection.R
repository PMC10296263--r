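#' Random-forest tuning configuration
#'
#' Grid and cross-validation settings for the anchor-prediction forest. The
#' defaults mirror the published analysis: mtry 5 to 50 in steps of 5,
#' extremely-randomized ("extratrees") splits, minimum node size 2 or 3,
#' 101 trees, and five repeats of 10-fold cross-validation, selecting by
#' RMSE.
#'
#' @param mtry_grid Candidate numbers of predictors sampled per split.
#' @param min_node_sizes Candidate minimum node sizes.
#' @param n_trees Trees per forest.
#' @param cv_folds,cv_repeats Folds and repeats of cross-validation.
#' @param selection_metric `"rmse"` or `"r_squared"`.
#' @param seed Integer seed; controls fold assignment and every forest.
#' @return An `rf_config` list. The split rule is always `"extratrees"`.
#' @export
rf_config <- function(mtry_grid = seq(5, 50, by = 5),
                      min_node_sizes = c(2, 3),
                      n_trees = 101,
                      cv_folds = 10,
                      cv_repeats = 5,
                      selection_metric = c("rmse", "r_squared"),
                      seed = 1L) {
  selection_metric <- match.arg(selection_metric)
  if (any(mtry_grid < 1) || any(min_node_sizes < 1) || n_trees < 1 ||
      cv_folds < 2 || cv_repeats < 1)
    stop("invalid rf_config: grid values, trees, folds and repeats must be positive")
  structure(list(mtry_grid = as.integer(mtry_grid),
                 split_rule = "extratrees",
                 min_node_sizes = as.integer(min_node_sizes),
                 n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 selection_metric = selection_metric,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Tune and fit the anchor-prediction forest
#'
#' Predicts the anchor gene's log expression from all other genes with
#' [ranger::ranger()] regression forests using extremely-randomized split
#' selection, grid-searching mtry x minimum node size by repeated k-fold
#' cross-validation, refitting the best model on all samples, and extracting
#' impurity (variance-reduction) variable importance rescaled so the maximum
#' equals 100.
#'
#' @param matrix A log-scale [expression_matrix()] containing the anchor.
#' @param anchor Anchor gene symbol; excluded from the predictor set.
#' @param config An [rf_config()]; mtry values above the number of
#'   predictors are dropped from the grid.
#' @return A list with `summary` (data frame: `best_mtry`,
#'   `best_min_node_size`, `cv_rmse`, `cv_r_squared`, `cv_mae`) and
#'   `importance` (data frame: `gene`, `importance` in \[0, 100\], sorted
#'   descending, ties broken by gene symbol).
#' @export
tune_and_fit <- function(matrix, anchor, config = rf_config()) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(config, "rf_config"))
  if (matrix$scale_state != "log") stop("tune_and_fit expects a log-scale matrix")
  if (!anchor %in% gene_ids(matrix)) stop("anchor gene '", anchor, "' not present")
  n <- ncol(matrix$values)
  if (n < config$cv_folds)
    stop("configuration error: fewer samples (", n, ") than folds (", config$cv_folds, ")")
  predictors <- setdiff(gene_ids(matrix), anchor)
  X <- t(matrix$values[predictors, , drop = FALSE])
  y <- matrix$values[anchor, ]
  mtry_grid <- config$mtry_grid[config$mtry_grid <= length(predictors)]
  if (!length(mtry_grid)) mtry_grid <- max(1L, floor(sqrt(length(predictors))))
  grid <- expand.grid(mtry = mtry_grid, min_node_size = config$min_node_sizes)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  # fold assignments fixed across the grid so candidates see identical splits
  folds <- lapply(seq_len(config$cv_repeats), function(rep)
    sample(rep_len(seq_len(config$cv_folds), n)))

  cv <- data.frame(grid, rmse = NA_real_, r_squared = NA_real_, mae = NA_real_)
  for (gi in seq_len(nrow(grid))) {
    pred <- rep(NA_real_, n)
    rmse_acc <- r2_acc <- mae_acc <- numeric(0)
    for (rep in seq_len(config$cv_repeats)) {
      fold_id <- folds[[rep]]
      pred_rep <- rep(NA_real_, n)
      for (k in seq_len(config$cv_folds)) {
        test <- fold_id == k
        if (!any(test) || sum(!test) < 2) next
        fit <- ranger::ranger(
          x = X[!test, , drop = FALSE], y = y[!test],
          num.trees = config$n_trees, mtry = grid$mtry[gi],
          splitrule = "extratrees", min.node.size = grid$min_node_size[gi],
          seed = config$seed + 1000L * rep + k, num.threads = 1)
        pred_rep[test] <- stats::predict(fit, data = X[test, , drop = FALSE])$predictions
      }
      ok <- !is.na(pred_rep)
      res <- y[ok] - pred_rep[ok]
      rmse_acc <- c(rmse_acc, sqrt(mean(res^2)))
      mae_acc <- c(mae_acc, mean(abs(res)))
      r2_acc <- c(r2_acc, stats::cor(y[ok], pred_rep[ok])^2)
    }
    cv$rmse[gi] <- mean(rmse_acc)
    cv$mae[gi] <- mean(mae_acc)
    cv$r_squared[gi] <- mean(r2_acc)
  }
  best <- if (config$selection_metric == "rmse")
    which.min(cv$rmse) else which.max(cv$r_squared)

  final <- ranger::ranger(
    x = X, y = y, num.trees = config$n_trees, mtry = cv$mtry[best],
    splitrule = "extratrees", min.node.size = cv$min_node_size[best],
    importance = "impurity", seed = config$seed, num.threads = 1)
  imp <- final$variable.importance
  scaled <- if (max(imp) > 0) 100 * imp / max(imp) else imp
  importance <- data.frame(gene = names(scaled), importance = unname(scaled),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance, importance$gene), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL

  list(
    summary = data.frame(best_mtry = cv$mtry[best],
                         best_min_node_size = cv$min_node_size[best],
                         cv_rmse = cv$rmse[best],
                         cv_r_squared = cv$r_squared[best],
                         cv_mae = cv$mae[best]),
    importance = importance,
    cv_grid = cv
  )
}

#' Intersect high-importance genes across cohorts
#'
#' Genes whose max-scaled importance is strictly greater than `threshold` in
#' both cohorts, sorted by the smaller of the two importances, descending.
#'
#' @param table_a,table_b Importance tables (`gene`, `importance`) as
#'   returned by [tune_and_fit()].
#' @param threshold Importance cutoff (strictly greater than).
#' @return Data frame `gene`, `importance_a`, `importance_b`.
#' @export
intersect_importance <- function(table_a, table_b, threshold = 40) {
  for (tab in list(table_a, table_b))
    if (!all(c("gene", "importance") %in% names(tab)))
      stop("importance tables need 'gene' and 'importance' columns")
  a <- table_a[table_a$importance > threshold, c("gene", "importance")]
  b <- table_b[table_b$importance > threshold, c("gene", "importance")]
  common <- intersect(a$gene, b$gene)
  out <- data.frame(gene = common,
                    importance_a = a$importance[match(common, a$gene)],
                    importance_b = b$importance[match(common, b$gene)],
                    stringsAsFactors = FALSE)
  keymin <- pmin(out$importance_a, out$importance_b)
  out <- out[order(-keymin, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
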