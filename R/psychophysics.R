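#' Paired-comparison schedule
#'
#' All ordered pairs of non-identical items: each unordered pair is presented
#' in both orders, giving `n (n - 1)` trials (90 for the 10 experimental
#' conditions, i.e. 45 unordered pairs in both orders).
#'
#' @param n_items Number of items (`>= 2`).
#' @return Data frame with integer columns `first` and `second`.
#' @export
pair_schedule <- function(n_items) {
  if (n_items < 2) stop("need at least 2 items")
  g <- expand.grid(first = seq_len(n_items), second = seq_len(n_items))
  g <- g[g$first != g$second, ]
  rownames(g) <- NULL
  g
}

#' Construct a paired-comparison win table
#'
#' @param wins Square integer matrix, `wins[i, j]` = number of times item `i`
#'   was judged more tonal than item `j`; zero diagonal.
#' @param items Item labels.
#' @return A `"paired_comparisons"` object.
#' @export
paired_comparisons <- function(wins, items = rownames(wins)) {
  wins <- as.matrix(wins)
  if (nrow(wins) != ncol(wins)) stop("wins must be square")
  if (any(wins < 0) || any(wins != round(wins))) {
    stop("wins must be non-negative integers")
  }
  if (any(diag(wins) != 0)) stop("diagonal of wins must be zero")
  if (is.null(items)) items <- paste0("item", seq_len(nrow(wins)))
  dimnames(wins) <- list(items, items)
  structure(list(wins = wins, items = items), class = "paired_comparisons")
}

# connectivity of the comparison graph (pairs with at least one presentation)
.comparison_connected <- function(n_pair) {
  n <- nrow(n_pair)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    nb <- which(n_pair[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Bradley-Terry-Luce scaling of paired comparisons
#'
#' Maximum-likelihood ratio-scale strengths `S` under the choice model
#' `P(i beats j) = S_i / (S_i + S_j)`, fitted by minorization-maximization
#' iteration to a convergence tolerance of `1e-8` and normalized to sum 1
#' (only strength ratios are identified; normalization fixes the gauge).
#' Items that win or lose every comparison they take part in have no finite
#' MLE; they are flagged, and `regularize = TRUE` adds 0.5 pseudo-wins to
#' every ordered pair to keep the estimate interior.
#'
#' @param table A `"paired_comparisons"` object or a win matrix.
#' @param tol Convergence tolerance on the strength vector.
#' @param max_iter Iteration cap.
#' @param regularize Add 0.5 pseudo-counts to every ordered pair.
#' @return A `"salience_scale"`: list with `strengths` (named, sum 1), `se`
#'   (approximate standard errors from the inverse Fisher information on log
#'   strengths), `boundary` (logical flags), `iterations`, `converged`.
#' @export
btl_fit <- function(table, tol = 1e-8, max_iter = 10000, regularize = FALSE) {
  if (!inherits(table, "paired_comparisons")) table <- paired_comparisons(table)
  w <- table$wins
  n <- nrow(w)
  n_pair <- w + t(w)
  involved <- rowSums(n_pair) > 0
  if (any(!involved)) stop("item with no comparisons: strengths inestimable")
  if (!.comparison_connected(n_pair)) {
    stop("comparison graph disconnected: strengths inestimable")
  }
  all_win <- rowSums(w) == rowSums(n_pair)
  all_lose <- rowSums(w) == 0
  boundary <- all_win | all_lose
  if (regularize) {
    off <- matrix(0.5, n, n)
    diag(off) <- 0
    off[n_pair == 0 & t(n_pair) == 0] <- 0
    w <- w + off
    n_pair <- w + t(w)
  }
  wi <- rowSums(w)
  s <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- vapply(seq_len(n), function(i) {
      j <- which(n_pair[i, ] > 0)
      sum(n_pair[i, j] / (s[i] + s[j]))
    }, numeric(1))
    s_new <- wi / denom
    s_new[!is.finite(s_new) | s_new <= 0] <- .Machine$double.xmin
    s_new <- s_new / sum(s_new)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  p <- outer(s, s, function(a, b) a / (a + b))
  h <- -n_pair * p * t(p)
  diag(h) <- 0
  diag(h) <- -rowSums(h)
  cov_eta <- MASS::ginv(h)
  se <- s * sqrt(pmax(diag(cov_eta), 0))
  names(s) <- names(se) <- table$items
  structure(list(strengths = s, se = se, boundary = boundary,
                 iterations = it, converged = converged),
            class = "salience_scale")
}

#' @export
print.salience_scale <- function(x, ...) {
  cat("<salience_scale (BTL, normalized to sum 1)>\n")
  print(round(x$strengths, 4))
  if (any(x$boundary)) {
    cat("boundary items:", paste(names(x$strengths)[x$boundary],
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fitted win probabilities of a BTL scale
#'
#' @param scale A `"salience_scale"`.
#' @return Matrix of `P(i beats j)`.
#' @export
btl_win_prob <- function(scale) {
  s <- scale$strengths
  outer(s, s, function(a, b) a / (a + b))
}

#' Salience asymmetry index per half-life
#'
#' Computes `AI_S = (S_ramped - S_damped) / (S_ramped + S_damped)` for every
#' half-life present in the scale.  Items must be named with
#' [condition_id()]-style labels (`"ramped_4"`, `"damped_0.5"`, ...).
#'
#' @param scale A `"salience_scale"` (or named strength vector).
#' @return Data frame with `half_life_ms`, `x_ramped`, `x_damped`, `ai`.
#' @export
salience_ai <- function(scale) {
  s <- if (inherits(scale, "salience_scale")) scale$strengths else scale
  labs <- names(s)
  m <- regmatches(labs, regexec("^(ramped|damped)_([0-9.]+)$", labs))
  ok <- lengths(m) == 3
  if (!all(ok)) stop("item labels must look like 'ramped_4' / 'damped_4'")
  type <- vapply(m, `[`, "", 2)
  hl <- as.numeric(vapply(m, `[`, "", 3))
  out <- lapply(sort(unique(hl)), function(h) {
    xr <- s[type == "ramped" & hl == h]
    xd <- s[type == "damped" & hl == h]
    if (length(xr) != 1 || length(xd) != 1) {
      stop("missing ramped or damped condition for half-life ", h)
    }
    data.frame(half_life_ms = h, x_ramped = unname(xr), x_damped = unname(xd),
               ai = asymmetry_index(unname(xr), unname(xd)))
  })
  do.call(rbind, out)
}

#' Read / write win tables as delimited text
#'
#' Tab-separated matrix with item labels as header row and first column.
#'
#' @param table A `"paired_comparisons"`.
#' @param path File path.
#' @return `write_win_table`: `path` invisibly; `read_win_table`: a
#'   `"paired_comparisons"`.
#' @export
write_win_table <- function(table, path) {
  stopifnot(inherits(table, "paired_comparisons"))
  utils::write.table(table$wins, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_win_table
#' @export
read_win_table <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  paired_comparisons(m)
}
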