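#' Reverse-mode automatic differentiation tape
#'
#' `adxrf` fits spectra by gradient descent on a scalar loss, and the gradients
#' come from a small reverse-mode automatic differentiation (AD) engine built
#' around a tape of elementary vector/matrix operations. Every arithmetic
#' operation on an [ad_var()] records a node holding the operation's parents
#' and a closure that maps the node's adjoint to its parents' adjoints;
#' [ad_backward()] then sweeps the tape once, accumulating exact gradients of
#' a scalar output with respect to every leaf variable.
#'
#' The engine supports exactly the primitives the spectrum model needs:
#' elementwise arithmetic (`+ - * / ^`), `exp`, `log`, `sqrt`, `sin`, `cos`,
#' `abs`, `sum`, `mean`, subsetting, the complementary error function
#' ([erfc()]) and its scaled variant ([erfcx()]), elementwise minima and
#' clamps, column/row broadcasting between vectors and matrices, row
#' totals, and a fractional-index linear-interpolation gather
#' ([gather_interp()]) used by the differentiable SNIP background.
#'
#' All primitives have plain-numeric default methods, so the same model code
#' runs on ordinary vectors (for fast evaluation) or on tape variables (for
#' gradients).
#'
#' @param x,v numeric value(s) for a leaf variable.
#' @param tape a tape created by `ad_tape()`.
#' @return `ad_tape()` returns a tape environment; `ad_var()` returns an
#'   object of class `"ad"` registered on the tape.
#' @examples
#' tp <- ad_tape()
#' x <- ad_var(tp, 2)
#' y <- x^2 + 3 * x
#' g <- ad_backward(y)
#' ad_grad_of(g, x) # dy/dx = 2x + 3 = 7
#' @name autodiff
NULL

#' @rdname autodiff
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$last <- NULL
  t$n <- 0L
  class(t) <- "ad_tape"
  t
}

# register a node; p holds parent ids (0 for non-ad parents), bk maps the
# node adjoint to a list of parent adjoints (NULL entries for id 0 parents).
# nodes form a cons list (newest first), which is exactly the traversal
# order of the backward sweep and appends in O(1) without copying
ad_node <- function(tape, value, p = integer(), bk = NULL) {
  n <- tape$n + 1L
  tape$n <- n
  tape$last <- list(id = n, p = p, bk = bk, prev = tape$last)
  x <- list(tape = tape, id = n, v = value)
  class(x) <- "ad"
  x
}

#' @rdname autodiff
#' @export
ad_var <- function(tape, x) {
  # leaves carry no backward closure and need no tape entry
  n <- tape$n + 1L
  tape$n <- n
  x <- list(tape = tape, id = n, v = x)
  class(x) <- "ad"
  x
}

#' Numeric value of a tape variable (identity on plain numerics)
#' @param x an `"ad"` object or numeric.
#' @export
ad_value <- function(x) if (inherits(x, "ad")) .subset2(x, "v") else x

is_ad <- function(x) inherits(x, "ad")

# reduce an adjoint to the shape of a (possibly scalar) parent
.red <- function(g, n) if (n == 1L && length(g) > 1L) sum(g) else g

#' Backward sweep: gradients of a scalar node
#'
#' @param loss an `"ad"` scalar (length-1 value).
#' @return a list of adjoints indexed by node id; extract with [ad_grad_of()].
#' @export
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$v) == 1L)
  nd <- loss$tape$last
  lid <- loss$id
  while (!is.null(nd) && nd$id > lid) nd <- nd$prev
  grads <- vector("list", lid)
  grads[[lid]] <- 1
  while (!is.null(nd)) {
    g <- grads[[nd$id]]
    if (!is.null(g) && !is.null(nd$bk)) {
      pg <- nd$bk(g)
      p <- nd$p
      for (j in seq_along(p)) {
        pj <- p[j]
        if (pj == 0L) next
        gj <- pg[[j]]
        if (is.null(gj)) next
        grads[[pj]] <- if (is.null(grads[[pj]])) gj else grads[[pj]] + gj
      }
    }
    nd <- nd$prev
  }
  grads
}

#' @rdname ad_backward
#' @param grads result of `ad_backward()`.
#' @param var the `"ad"` leaf whose gradient is wanted.
#' @export
ad_grad_of <- function(grads, var) {
  g <- if (var$id <= length(grads)) grads[[var$id]] else NULL
  if (is.null(g)) {
    g <- ad_value(var) * 0
  }
  g
}

#' @export
Ops.ad <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "+") return(e1)
    if (.Generic == "-") {
      return(ad_node(.subset2(e1, "tape"), -.subset2(e1, "v"),
                     .subset2(e1, "id"), function(g) list(-g)))
    }
    stop("unsupported unary op for ad: ", .Generic)
  }
  a1 <- inherits(e1, "ad")
  a2 <- inherits(e2, "ad")
  v1 <- if (a1) .subset2(e1, "v") else e1
  v2 <- if (a2) .subset2(e2, "v") else e2
  op <- .Generic
  if (op == "==" || op == "!=" || op == "<" || op == "<=" ||
      op == ">" || op == ">=") {
    return(get(op)(v1, v2))
  }
  tape <- if (a1) .subset2(e1, "tape") else .subset2(e2, "tape")
  p <- c(if (a1) .subset2(e1, "id") else 0L,
         if (a2) .subset2(e2, "id") else 0L)
  n1 <- length(v1); n2 <- length(v2)
  switch(op,
    "+" = ad_node(tape, v1 + v2, p, function(g) {
      list(if (a1) .red(g, n1), if (a2) .red(g, n2))
    }),
    "-" = ad_node(tape, v1 - v2, p, function(g) {
      list(if (a1) .red(g, n1), if (a2) .red(-g, n2))
    }),
    "*" = ad_node(tape, v1 * v2, p, function(g) {
      list(if (a1) .red(g * v2, n1), if (a2) .red(g * v1, n2))
    }),
    "/" = ad_node(tape, v1 / v2, p, function(g) {
      list(if (a1) .red(g / v2, n1), if (a2) .red(-g * v1 / (v2 * v2), n2))
    }),
    "^" = {
      val <- v1^v2
      ad_node(tape, val, p, function(g) {
        list(
          if (a1) .red(g * v2 * v1^(v2 - 1), n1),
          if (a2) .red(g * val * log(v1), n2)
        )
      })
    },
    stop("unsupported op for ad: ", op)
  )
}

#' @export
Math.ad <- function(x, ...) {
  v <- .subset2(x, "v")
  tape <- .subset2(x, "tape")
  id <- .subset2(x, "id")
  switch(.Generic,
    exp = {
      val <- exp(v)
      ad_node(tape, val, id, function(g) list(g * val))
    },
    log = ad_node(tape, log(v), id, function(g) list(g / v)),
    sqrt = {
      val <- sqrt(v)
      ad_node(tape, val, id, function(g) list(g / (2 * val)))
    },
    abs = ad_node(tape, abs(v), id, function(g) list(g * sign(v))),
    sin = ad_node(tape, sin(v), id, function(g) list(g * cos(v))),
    cos = ad_node(tape, cos(v), id, function(g) list(-g * sin(v))),
    stop("unsupported math function for ad: ", .Generic)
  )
}

#' @export
Summary.ad <- function(..., na.rm = FALSE) {
  args <- list(...)
  if (length(args) != 1L) stop("ad summaries take a single argument")
  x <- args[[1L]]
  v <- x$v
  switch(.Generic,
    sum = ad_node(x$tape, sum(v), x$id, function(g) list(rep(g, length(v)))),
    max = max(v),
    min = min(v),
    stop("unsupported summary for ad: ", .Generic)
  )
}

#' @export
mean.ad <- function(x, ...) sum(x) / length(x$v)

#' @export
length.ad <- function(x) length(x$v)

#' @export
`[.ad` <- function(x, i) {
  v <- x$v
  idx <- if (is.logical(i)) which(i) else as.integer(i)
  n <- length(v)
  ad_node(x$tape, v[idx], x$id, function(g) {
    list(.scatter_add(n, idx, g))
  })
}

#' Complementary error function (AD-aware generic)
#' @param x numeric or `"ad"`.
#' @export
erfc <- function(x) UseMethod("erfc")

#' @export
erfc.default <- function(x) pracma::erfc(x)

#' @export
erfc.ad <- function(x) {
  v <- x$v
  ad_node(x$tape, pracma::erfc(v), x$id, function(g) {
    list(g * (-2 / sqrt(pi)) * exp(-v * v))
  })
}

#' Scaled complementary error function exp(x^2) erfc(x) (AD-aware generic)
#' @param x numeric or `"ad"`.
#' @export
erfcx <- function(x) UseMethod("erfcx")

#' @export
erfcx.default <- function(x) pracma::erfcx(x)

#' @export
erfcx.ad <- function(x) {
  v <- x$v
  val <- pracma::erfcx(v)
  ad_node(x$tape, val, x$id, function(g) {
    list(g * (2 * v * val - 2 / sqrt(pi)))
  })
}

#' Elementwise minimum of two arguments (AD-aware generic)
#' @param a,b numeric or `"ad"`, equal shape or scalar.
#' @export
pmin2 <- function(a, b) UseMethod("pmin2")

#' @export
pmin2.default <- function(a, b) {
  if (is_ad(b)) return(pmin2.ad(a, b))
  pmin(a, b)
}

#' @export
pmin2.ad <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  m <- va <= vb
  tape <- if (is_ad(a)) a$tape else b$tape
  p <- c(if (is_ad(a)) a$id else 0L, if (is_ad(b)) b$id else 0L)
  na <- length(va); nb <- length(vb)
  ad_node(tape, pmin(va, vb), p, function(g) {
    list(
      if (is_ad(a)) .red(g * m, na),
      if (is_ad(b)) .red(g * !m, nb)
    )
  })
}

#' Clamp values to an interval (AD-aware generic; gradient 0 where clamped)
#' @param x numeric or `"ad"`.
#' @param lo,hi numeric bounds.
#' @export
ad_clamp <- function(x, lo, hi) UseMethod("ad_clamp")

#' @export
ad_clamp.default <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
ad_clamp.ad <- function(x, lo, hi) {
  v <- x$v
  inside <- (v >= lo) & (v <= hi)
  ad_node(x$tape, pmin(pmax(v, lo), hi), x$id, function(g) list(g * inside))
}

#' Broadcast a length-n vector across k columns (AD-aware generic)
#' @param v numeric or `"ad"` vector.
#' @param k number of columns.
#' @export
bcast_cols <- function(v, k) UseMethod("bcast_cols")

#' @export
bcast_cols.default <- function(v, k) matrix(v, length(v), k)

#' @export
bcast_cols.ad <- function(v, k) {
  x <- v$v
  n <- length(x)
  ad_node(v$tape, matrix(x, n, k), v$id, function(g) {
    dim(g) <- c(n, k)
    list(rowSums(g))
  })
}

#' Broadcast a length-k vector across n rows (AD-aware generic)
#' @param v numeric or `"ad"` vector.
#' @param n number of rows.
#' @export
bcast_rows <- function(v, n) UseMethod("bcast_rows")

#' @export
bcast_rows.default <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' @export
bcast_rows.ad <- function(v, n) {
  x <- v$v
  k <- length(x)
  ad_node(v$tape, matrix(x, n, k, byrow = TRUE), v$id, function(g) {
    dim(g) <- c(n, k)
    list(colSums(g))
  })
}

#' Row totals of a matrix (AD-aware generic)
#' @param m numeric matrix or `"ad"` matrix.
#' @export
row_total <- function(m) UseMethod("row_total")

#' @export
row_total.default <- function(m) rowSums(m)

#' @export
row_total.ad <- function(m) {
  v <- m$v
  n <- nrow(v); k <- ncol(v)
  ad_node(m$tape, rowSums(v), m$id, function(g) {
    list(matrix(g, n, k))
  })
}

# scatter-accumulate weights w at (possibly repeated) indices idx into
# a length-n vector
.scatter_add <- function(n, idx, w) cpp_wbincount(as.integer(idx), w, n)

#' Fractional-index gather with linear interpolation (AD-aware generic)
#'
#' Reads `v` at real-valued positions `pos` (1-based), linearly interpolating
#' between neighbouring entries; positions are clamped to `[1, length(v)]`.
#' For integer positions this is exact indexing. Gradients propagate both to
#' the gathered vector and to the positions (slope of the interpolant), which
#' is what keeps window widths differentiable inside the SNIP background.
#'
#' @param v numeric or `"ad"` vector to read.
#' @param pos numeric or `"ad"` vector of positions.
#' @export
gather_interp <- function(v, pos) UseMethod("gather_interp")

#' @export
gather_interp.default <- function(v, pos) {
  if (is_ad(pos)) return(.gather_interp_ad(v, pos))
  .gi_parts(v, pos)$val
}

#' @export
gather_interp.ad <- function(v, pos) .gather_interp_ad(v, pos)

.gi_parts <- function(vv, pv) {
  n <- length(vv)
  inside <- (pv >= 1) & (pv <= n)
  p <- pmin(pmax(pv, 1), n)
  f <- floor(p)
  f[f >= n] <- n - 1L
  f <- as.integer(f)
  t <- p - f
  list(
    val = vv[f] * (1 - t) + vv[f + 1L] * t,
    f = f, t = t, slope = vv[f + 1L] - vv[f], inside = inside, n = n
  )
}

.gather_interp_ad <- function(v, pos) {
  av <- is_ad(v); ap <- is_ad(pos)
  vv <- ad_value(v); pv <- ad_value(pos)
  parts <- .gi_parts(vv, pv)
  tape <- if (av) v$tape else pos$tape
  p <- c(if (av) v$id else 0L, if (ap) pos$id else 0L)
  f <- parts$f; t <- parts$t; n <- parts$n
  ad_node(tape, parts$val, p, function(g) {
    list(
      if (av) {
        .scatter_add(n, f, g * (1 - t)) + .scatter_add(n, f + 1L, g * t)
      },
      if (ap) g * parts$slope * parts$inside
    )
  })
}

#' Boxcar (moving-average) smoothing with replicated edges (AD-aware)
#' @param v numeric or `"ad"` vector.
#' @param width odd window width in channels.
#' @export
boxcar_smooth <- function(v, width) UseMethod("boxcar_smooth")

#' @export
boxcar_smooth.default <- function(v, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  cpp_boxcar_f(v, as.integer(width))
}

#' @export
boxcar_smooth.ad <- function(v, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  width <- as.integer(width)
  ad_node(v$tape, cpp_boxcar_f(v$v, width), v$id,
          function(g) list(cpp_boxcar_b(g, width)))
}

#' Replace non-finite and negative entries by zero (AD-aware generic)
#' @param x numeric or `"ad"`.
#' @export
clean_nonneg <- function(x) UseMethod("clean_nonneg")

#' @export
clean_nonneg.default <- function(x) {
  x[!is.finite(x) | x < 0] <- 0
  x
}

#' @export
clean_nonneg.ad <- function(x) {
  v <- x$v
  ok <- is.finite(v) & v >= 0
  v2 <- v
  v2[!ok] <- 0
  ad_node(x$tape, v2, x$id, function(g) list(g * ok))
}

#' Scatter a vector into a longer zero vector (AD-aware generic)
#' @param n length of the output vector.
#' @param idx integer positions (no duplicates).
#' @param x numeric or `"ad"` values to place at `idx`.
#' @export
scatter_into <- function(n, idx, x) UseMethod("scatter_into", x)

#' @export
scatter_into.default <- function(n, idx, x) {
  out <- numeric(n)
  out[idx] <- x
  out
}

#' @export
scatter_into.ad <- function(n, idx, x) {
  out <- numeric(n)
  out[idx] <- x$v
  ad_node(x$tape, out, x$id, function(g) list(g[idx]))
}

#' @export
print.ad <- function(x, ...) {
  cat("<ad node", x$id, "len", length(x$v), ">\n")
  invisible(x)
}
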