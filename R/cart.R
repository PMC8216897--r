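#' Classification tree (CART) with Gini or cross-entropy splits
#'
#' Greedy binary recursive partitioning: at each node every covariate is
#' scanned over candidate thresholds (midpoints of consecutive sorted
#' unique values) and the split minimizing the weighted child impurity is
#' taken (Gini `1 - sum p^2`, or cross-entropy `-sum p log p`). Cases go
#' left when `value < threshold` and right when `value >= threshold`.
#' Splitting stops at `max_depth`, when a child would fall below
#' `min_leaf`, or when no split improves impurity. Ties in impurity are
#' broken by lowest covariate index, then lowest threshold. Leaves record
#' the class distribution and the percentage of all training data they
#' hold.
#'
#' @param features data frame (or matrix) of numeric covariates, one row
#'   per case.
#' @param labels character/factor response, one per row; a single-label
#'   input yields a single-leaf tree.
#' @param max_depth maximum tree depth (root = depth 0), default 4.
#' @param min_leaf minimum cases per leaf; a fraction in (0, 1) is read as
#'   a share of the training size (default 0.05).
#' @param criterion "gini" or "cross_entropy".
#' @return Object of class `eha_cart`: nested node list plus metadata.
#'   `tidy()` returns one row per node; `print()` renders the indented
#'   rule text with per-leaf data percentages.
#' @export
fit_cart <- function(features, labels, max_depth = 4, min_leaf = 0.05,
                     criterion = c("gini", "cross_entropy")) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(features)
  stopifnot(nrow(X) >= 1, all(vapply(X, is.numeric, TRUE)),
            all(is.finite(as.matrix(X))))
  y <- as.character(labels)
  stopifnot(length(y) == nrow(X))
  n_total <- nrow(X)
  if (min_leaf < 1) min_leaf <- max(1L, floor(min_leaf * n_total))
  min_leaf <- as.integer(min_leaf)
  classes <- sort(unique(y))

  impurity <- function(counts) {
    p <- counts / sum(counts)
    p <- p[p > 0]
    if (criterion == "gini") 1 - sum(p^2) else -sum(p * log(p))
  }

  best_split <- function(idx) {
    yc <- y[idx]
    best <- NULL
    for (j in seq_along(X)) {
      v <- X[idx, j]
      uv <- sort(unique(v))
      if (length(uv) < 2) next
      thresholds <- (uv[-1] + uv[-length(uv)]) / 2
      for (thr in thresholds) {
        left <- v < thr
        nl <- sum(left); nr <- length(v) - nl
        if (nl < min_leaf || nr < min_leaf) next
        imp <- (nl * impurity(table(yc[left])) +
                nr * impurity(table(yc[!left]))) / length(v)
        if (is.null(best) || imp < best$imp - 1e-12) {
          best <- list(var = j, threshold = thr, imp = imp)
        }
        # ties: keep earlier covariate / lower threshold (scan order)
      }
    }
    best
  }

  grow <- function(idx, depth) {
    counts <- table(factor(y[idx], levels = classes))
    node_imp <- impurity(counts)
    leaf <- list(
      type = "leaf",
      prediction = classes[which.max(counts)],
      counts = as.integer(counts),
      impurity = node_imp,
      n = length(idx),
      pct_of_data = 100 * length(idx) / n_total
    )
    if (depth >= max_depth || node_imp <= 0 || length(idx) < 2 * min_leaf) {
      return(leaf)
    }
    sp <- best_split(idx)
    if (is.null(sp) || sp$imp >= node_imp - 1e-12) return(leaf)
    left <- idx[X[idx, sp$var] < sp$threshold]
    right <- setdiff(idx, left)
    list(
      type = "node",
      var = names(X)[sp$var],
      var_index = sp$var,
      threshold = sp$threshold,
      impurity = node_imp,
      n = length(idx),
      pct_of_data = 100 * length(idx) / n_total,
      left = grow(left, depth + 1),
      right = grow(right, depth + 1)
    )
  }

  structure(
    list(root = grow(seq_len(n_total), 0), classes = classes,
         criterion = criterion, max_depth = max_depth, min_leaf = min_leaf,
         n = n_total, covariates = names(X)),
    class = "eha_cart"
  )
}

#' Predict from a fitted classification tree
#'
#' Deterministic root-to-leaf descent; at each node the case goes left iff
#' `value < threshold` (a value exactly at the threshold goes right).
#'
#' @param object an `eha_cart`.
#' @param newdata data frame containing every covariate the tree uses.
#' @param ... unused.
#' @return Tibble `prediction` (class label) and `leaf_pct_of_data`.
#' @export
predict.eha_cart <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  missing_cov <- setdiff(tree_vars(object$root), names(nd))
  if (length(missing_cov)) {
    stop("missing covariate value(s): ", paste(missing_cov, collapse = ", "))
  }
  one <- function(node, row) {
    while (node$type == "node") {
      v <- nd[row, node$var]
      if (!is.finite(v)) stop("missing covariate value: ", node$var)
      node <- if (v < node$threshold) node$left else node$right
    }
    c(node$prediction, node$pct_of_data)
  }
  out <- t(vapply(seq_len(nrow(nd)), function(r) one(object$root, r),
                  c("", "")))
  tibble::tibble(prediction = out[, 1],
                 leaf_pct_of_data = as.numeric(out[, 2]))
}

tree_vars <- function(node) {
  if (node$type == "leaf") return(character())
  unique(c(node$var, tree_vars(node$left), tree_vars(node$right)))
}

tree_nodes <- function(node, id = 1L, depth = 0L) {
  row <- tibble::tibble(
    id = id, depth = depth, type = node$type,
    var = if (node$type == "node") node$var else NA_character_,
    threshold = if (node$type == "node") node$threshold else NA_real_,
    prediction = if (node$type == "leaf") node$prediction else NA_character_,
    impurity = node$impurity, n = node$n, pct_of_data = node$pct_of_data
  )
  if (node$type == "leaf") return(row)
  left <- tree_nodes(node$left, id * 2L, depth + 1L)
  right <- tree_nodes(node$right, id * 2L + 1L, depth + 1L)
  dplyr::bind_rows(row, left, right)
}

#' @export
tidy.eha_cart <- function(x, ...) tree_nodes(x$root)

#' @export
glance.eha_cart <- function(x, ...) {
  nodes <- tree_nodes(x$root)
  tibble::tibble(
    n = x$n, n_leaves = sum(nodes$type == "leaf"),
    depth = max(nodes$depth), criterion = x$criterion,
    root_impurity = nodes$impurity[1]
  )
}

#' @export
print.eha_cart <- function(x, ...) {
  cat(sprintf("<eha_cart> %s tree, n = %d, %d classes\n",
              x$criterion, x$n, length(x$classes)))
  render <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s-> %s (%.1f%% of data, n = %d)\n",
                  pad, node$prediction, node$pct_of_data, node$n))
    } else {
      cat(sprintf("%sif %s < %.4g:\n", pad, node$var, node$threshold))
      render(node$left, indent + 1)
      cat(sprintf("%selse (%s >= %.4g):\n", pad, node$var, node$threshold))
      render(node$right, indent + 1)
    }
  }
  render(x$root, 0)
  invisible(x)
}

#' Write a fitted tree as JSON
#'
#' @param tree an `eha_cart`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cart_json <- function(tree, path) {
  jsonlite::write_json(
    list(criterion = tree$criterion, n = tree$n, classes = tree$classes,
         root = tree$root),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
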