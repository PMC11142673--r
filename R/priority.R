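#' Priority-index feature specification
#'
#' The ordered variable set entering the corridor priority index, each
#' drawn from the corridor, start-node, or end-node attribute tables. The
#' default reflects the design premise that shorter, protected, intact
#' corridors linking large lowland reserves to large, protected,
#' topographically diverse highland patches rank highest: corridor length
#' is inverted (shorter is better); all other variables enter positively.
#' `drop_rank` marks the designated victim of each collinear pair found by
#' [screen_collinear()] (the overlapping-protected-areas count and the
#' end-node area, which track corridor length and end-node elevational
#' range). The set is fully user-overridable.
#'
#' @param table optional replacement data.frame with columns `variable`,
#'   `source` (`"corridor"`, `"start"`, `"end"`), `column` (column in the
#'   source table), `invert`, `include`, `drop_rank`.
#' @return A data.frame of class `feature_spec`.
#' @export
feature_spec <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      variable = c("length_km", "elev_range", "protection", "n_pas",
                   "n_kbas", "mean_biomass", "start_area",
                   "start_elev_range", "end_area", "end_elev_range",
                   "end_protection"),
      source = c(rep("corridor", 6), "start", "start", "end", "end", "end"),
      column = c("length_km", "elev_range", "protection", "n_pas",
                 "n_kbas", "mean_biomass", "area_km2", "elev_range",
                 "area_km2", "elev_range", "protection"),
      invert = c(TRUE, rep(FALSE, 10)),
      include = TRUE,
      drop_rank = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
      stringsAsFactors = FALSE)
  }
  need <- c("variable", "source", "column", "invert", "include", "drop_rank")
  if (!all(need %in% names(table)))
    stop("feature spec needs columns: ", paste(need, collapse = ", "))
  if (sum(table$include) < 2)
    stop("at least two variables must be included")
  class(table) <- c("feature_spec", "data.frame")
  table
}

#' Assemble the corridor feature matrix
#'
#' Joins each corridor row to its start node and end patch and builds the
#' feature matrix in spec order, negating invert-flagged variables.
#' Corridors with unreachable status are excluded with a message; missing
#' joins are an error (no imputation).
#'
#' @param corridor_table data.frame from [corridor_metrics()].
#' @param start_table,end_table data.frames from [node_metrics()].
#' @param spec a [feature_spec()].
#' @return A numeric matrix (rows = corridors, named by `corridor_id`).
#' @export
assemble_features <- function(corridor_table, start_table, end_table,
                              spec = feature_spec()) {
  spec <- feature_spec(spec)
  spec <- spec[spec$include, , drop = FALSE]
  bad <- corridor_table$status != "ok"
  if (any(bad)) {
    message(sprintf("excluding %d corridor(s) without metrics", sum(bad)))
    corridor_table <- corridor_table[!bad, , drop = FALSE]
  }
  si <- match(corridor_table$start_id, start_table$reserve_id)
  if (anyNA(si))
    stop("corridor(s) with no matching start node: ",
         paste(unique(corridor_table$corridor_id[is.na(si)]), collapse = ", "))
  ei <- match(corridor_table$patch_id, end_table$patch_id)
  if (anyNA(ei))
    stop("corridor(s) with no matching end patch: ",
         paste(unique(corridor_table$corridor_id[is.na(ei)]), collapse = ", "))
  cols <- lapply(seq_len(nrow(spec)), function(j) {
    src <- switch(spec$source[j],
                  corridor = corridor_table,
                  start = start_table[si, , drop = FALSE],
                  end = end_table[ei, , drop = FALSE],
                  stop("unknown source: ", spec$source[j]))
    if (!spec$column[j] %in% names(src))
      stop(sprintf("variable %s: column %s not found in %s table",
                   spec$variable[j], spec$column[j], spec$source[j]))
    v <- as.numeric(src[[spec$column[j]]])
    if (spec$invert[j]) -v else v
  })
  X <- do.call(cbind, cols)
  dimnames(X) <- list(corridor_table$corridor_id, spec$variable)
  attr(X, "drop_rank") <- setNames(spec$drop_rank, spec$variable)
  X
}

#' Screen collinear variables
#'
#' Computes pairwise Spearman correlations and, for every pair with
#' `|rho| >= rho_threshold` (pairs handled in decreasing `|rho|`), removes
#' the pair member with the higher `drop_rank` (ties: the later column).
#' The report lists each flagged pair, its rho, and the decision.
#'
#' @param X feature matrix from [assemble_features()] (>= 3 rows).
#' @param rho_threshold absolute Spearman threshold (default 0.7).
#' @param drop_rank named numeric vector of drop preferences; defaults to
#'   the `drop_rank` attribute of `X` (zero when absent).
#' @return A list with `matrix` (reduced columns) and `report` (data.frame
#'   `var1`, `var2`, `rho`, `dropped`).
#' @export
screen_collinear <- function(X, rho_threshold = 0.7, drop_rank = NULL) {
  if (nrow(X) < 3) stop("need at least 3 rows to screen correlations")
  if (is.null(drop_rank)) drop_rank <- attr(X, "drop_rank")
  if (is.null(drop_rank)) drop_rank <- setNames(rep(0, ncol(X)), colnames(X))
  vars <- colnames(X)
  rho <- suppressWarnings(cor(X, method = "spearman"))
  pairs <- which(upper.tri(rho) & abs(rho) >= rho_threshold, arr.ind = TRUE)
  report <- data.frame(var1 = character(0), var2 = character(0),
                       rho = numeric(0), dropped = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(rho[pairs]))
    dropped <- character(0)
    for (p in ord) {
      v1 <- vars[pairs[p, 1]]; v2 <- vars[pairs[p, 2]]
      if (v1 %in% dropped || v2 %in% dropped) next
      r1 <- if (v1 %in% names(drop_rank)) drop_rank[[v1]] else 0
      r2 <- if (v2 %in% names(drop_rank)) drop_rank[[v2]] else 0
      victim <- if (r1 > r2) v1 else v2  # tie: later column
      dropped <- c(dropped, victim)
      report <- rbind(report,
                      data.frame(var1 = v1, var2 = v2,
                                 rho = rho[pairs[p, 1], pairs[p, 2]],
                                 dropped = victim, stringsAsFactors = FALSE))
    }
    X <- X[, setdiff(vars, dropped), drop = FALSE]
  }
  list(matrix = X, report = report)
}

#' Standardize the feature matrix
#'
#' Centers every column to mean 0 and scales to standard deviation 1
#' (n - 1 divisor). Constant columns are an error.
#'
#' @param X numeric feature matrix.
#' @return The z-matrix with attributes `means` and `sds`.
#' @export
standardize_features <- function(X) {
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, means), 2, sds, "/")
  attr(Z, "means") <- means
  attr(Z, "sds") <- sds
  Z
}

#' Fit the priority PCA model
#'
#' Principal component analysis of the standardized feature matrix
#' (eigendecomposition of the correlation structure). The priority index
#' uses the first `n_components` components (default 3); the model records
#' loadings, eigenvalues, and the fraction of variance those components
#' explain.
#'
#' @param Z z-matrix from [standardize_features()].
#' @param n_components retained components (default 3).
#' @param class_thresholds `c(low_upper, high_lower)` priority-index class
#'   cuts (default `c(2, 4)`).
#' @return An object of class `priority_model`.
#' @export
fit_priority_pca <- function(Z, n_components = 3,
                             class_thresholds = c(2, 4)) {
  if (nrow(Z) <= ncol(Z))
    warning("fewer rows than columns + 1; PCA may be unstable")
  pca <- prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pca$sdev^2
  rank <- sum(eig > max(eig) * 1e-10)
  if (rank < min(n_components, ncol(Z)))
    warning(sprintf("matrix rank %d below requested %d components; extra components dropped",
                    rank, n_components))
  k <- min(n_components, rank, ncol(Z))
  structure(list(loadings = pca$rotation, eigenvalues = eig,
                 n_components = k,
                 variance_explained = sum(eig[seq_len(k)]) / sum(eig),
                 variables = colnames(Z),
                 means = attr(Z, "means"), sds = attr(Z, "sds"),
                 class_thresholds = class_thresholds),
            class = "priority_model")
}

#' @export
print.priority_model <- function(x, ...) {
  cat(sprintf("<priority_model> %d variables, %d components retained (%.1f%% of variance)\n",
              length(x$variables), x$n_components,
              100 * x$variance_explained))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Corridor priority scores
#'
#' Projects the z-matrix on the retained components and computes the
#' priority index of each corridor as its Euclidean distance from the
#' origin in that component space, then classifies it. Note that the
#' distance is direction-blind: a corridor extreme on the unfavorable side
#' of a component also scores high.
#'
#' @param model a [fit_priority_pca()] model.
#' @param Z the z-matrix the model was fitted to (or new data standardized
#'   with the same parameters).
#' @return A data.frame: `corridor_id`, one score column per retained
#'   component (`pc1`, ...), `index`, `class`.
#' @export
priority_scores <- function(model, Z) {
  if (!identical(colnames(Z), model$variables))
    stop("z-matrix columns do not match the fitted model")
  k <- model$n_components
  S <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  index <- sqrt(rowSums(S^2))
  ids <- rownames(Z)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Z)))
  out <- data.frame(corridor_id = ids, S, index = index,
                    class = classify_priority(index,
                                              model$class_thresholds[1],
                                              model$class_thresholds[2]),
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(k)] <- paste0("pc", seq_len(k))
  rownames(out) <- NULL
  out
}

#' Classify priority index values
#'
#' Low on `[0, low_upper)`, medium on `[low_upper, high_lower]` (both ends
#' inclusive), high above `high_lower`.
#'
#' @param index non-negative index values.
#' @param low_upper,high_lower class cuts (defaults 2 and 4).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_priority <- function(index, low_upper = 2, high_lower = 4) {
  if (any(index < 0)) stop("priority index values must be non-negative")
  cls <- ifelse(index < low_upper, "low",
                ifelse(index <= high_lower, "medium", "high"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Full priority-index computation
#'
#' Convenience wrapper: assemble the feature matrix, screen collinear
#' variables, standardize, fit the PCA, and score every corridor.
#'
#' @inheritParams assemble_features
#' @param rho_threshold collinearity screen threshold.
#' @param n_components retained components.
#' @param class_thresholds class cuts `c(low_upper, high_lower)`.
#' @return A list with `scores`, `model`, and `screen_report`.
#' @export
compute_priority <- function(corridor_table, start_table, end_table,
                             spec = feature_spec(), rho_threshold = 0.7,
                             n_components = 3, class_thresholds = c(2, 4)) {
  X <- assemble_features(corridor_table, start_table, end_table, spec)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    message("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    dr <- attr(X, "drop_rank")
    X <- X[, sds > 0, drop = FALSE]
    attr(X, "drop_rank") <- dr[colnames(X)]
    if (ncol(X) < 2) stop("fewer than 2 non-constant variables remain")
  }
  scr <- screen_collinear(X, rho_threshold)
  Z <- standardize_features(scr$matrix)
  model <- fit_priority_pca(Z, n_components, class_thresholds)
  list(scores = priority_scores(model, Z), model = model,
       screen_report = scr$report)
}
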