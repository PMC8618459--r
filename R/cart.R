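# CART regression tree, written in-package because no tree package is
# available in the target environment. Splits minimize within-node SSE;
# defaults mirror the common library defaults (unlimited depth, split nodes
# down to 2 rows), under which the tree interpolates its training data.

cart_split <- function(X, y) {
  n <- length(y)
  best <- list(gain = 0, var = NA_integer_, val = NA_real_)
  sse <- function(s, s2, m) s2 - s^2 / m
  tot_s <- sum(y); tot_s2 <- sum(y^2)
  parent <- sse(tot_s, tot_s2, n)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]; ys <- y[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    valid <- which(diff(xs) > 0)          # split between distinct values
    if (!length(valid)) next
    m <- valid
    left <- sse(cs[m], cs2[m], m)
    right <- sse(tot_s - cs[m], tot_s2 - cs2[m], n - m)
    gain <- parent - (left + right)
    gi <- which.max(gain)
    if (gain[gi] > best$gain + 1e-12) {
      best <- list(gain = gain[gi], var = j,
                   val = (xs[m[gi]] + xs[m[gi] + 1]) / 2)
    }
  }
  best
}

cart_grow <- function(X, y, depth, max_depth, min_split, min_bucket) {
  n <- length(y)
  leaf <- list(leaf = TRUE, value = mean(y), n = n)
  if (n < min_split || depth >= max_depth || stats::var(y) == 0) return(leaf)
  sp <- cart_split(X, y)
  if (is.na(sp$var)) return(leaf)
  go_left <- X[, sp$var] <= sp$val
  if (sum(go_left) < min_bucket || sum(!go_left) < min_bucket) return(leaf)
  list(leaf = FALSE, var = sp$var, val = sp$val,
       left = cart_grow(X[go_left, , drop = FALSE], y[go_left],
                        depth + 1, max_depth, min_split, min_bucket),
       right = cart_grow(X[!go_left, , drop = FALSE], y[!go_left],
                         depth + 1, max_depth, min_split, min_bucket))
}

#' Fit / predict a CART regression tree
#'
#' Minimal in-package CART: binary splits chosen to maximize the reduction
#' in squared error, grown depth-first. With the defaults (no depth limit,
#' `min_split = 2`) the tree fits its training rows exactly wherever feature
#' vectors are distinct.
#'
#' @param X Numeric matrix of per-day feature rows.
#' @param y Numeric response.
#' @param max_depth,min_split,min_bucket Growth controls.
#' @return An object of class `cart_tree`.
#' @export
cart_fit <- function(X, y, max_depth = Inf, min_split = 2L, min_bucket = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) >= 1)
  structure(list(root = cart_grow(X, y, 0L, max_depth, min_split, min_bucket),
                 p = ncol(X)),
            class = "cart_tree")
}

#' @param object A `cart_tree`.
#' @param newdata Matrix of rows to predict.
#' @param ... Unused.
#' @rdname cart_fit
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  walk <- function(node, idx) {
    if (node$leaf || !length(idx)) {
      out[idx] <<- node$value
      return(invisible())
    }
    left <- newdata[idx, node$var] <= node$val
    walk(node$left, idx[left])
    walk(node$right, idx[!left])
  }
  out <- numeric(nrow(newdata))
  walk(object$root, seq_len(nrow(newdata)))
  out
}
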