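# Reverse-mode automatic differentiation on dense arrays.
#
# A node is an environment holding a value (`v`), an accumulated gradient
# (`g`, filled during the backward sweep) and, while a tape is active, a
# backward closure that scatters the node's gradient into its parents.
# Feature maps use the CHWN layout: dim = c(channels, height, width, batch);
# token sets are plain (tokens x dim) matrices. Ops accept either nodes or
# plain numeric arrays (treated as constants).

.ad <- new.env(parent = emptyenv())
.ad$recording <- FALSE
.ad$tape <- NULL
.ad$n <- 0L

is_node <- function(x) inherits(x, "ad_node")
val <- function(x) if (is_node(x)) x$v else x

ad_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  if (.ad$recording && !is.null(backward)) {
    nd$bw <- backward
    n <- .ad$n + 1L
    if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[n]] <- nd
    .ad$n <- n
  }
  class(nd) <- "ad_node"
  nd
}

#' Create a trainable parameter node
#' @param value numeric array with the parameter's initial value.
#' @return an `ad_node` whose gradient accumulates during [ad_backward()].
#' @keywords internal
#' @export
ad_param <- function(value) {
  nd <- ad_node(value)
  nd$is_param <- TRUE
  nd
}

# accumulate gradient g into node p (no-op for constants)
acc <- function(p, g) {
  if (!is_node(p)) return(invisible(NULL))
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

#' Start recording operations on a fresh tape
#' @keywords internal
#' @export
ad_begin_tape <- function() {
  .ad$tape <- vector("list", 2048L)
  .ad$n <- 0L
  .ad$recording <- TRUE
  invisible(NULL)
}

#' Backward sweep: populate gradients of everything reachable from `loss`
#' @param loss scalar-valued `ad_node`.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$v) == 1)
  .ad$recording <- FALSE
  loss$g <- 1
  for (i in seq.int(.ad$n, 1L)) {
    nd <- .ad$tape[[i]]
    if (!is.null(nd$g)) nd$bw(nd$g)
    nd$bw <- NULL  # release closure memory as we go
  }
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

#' Stop recording and drop the tape (e.g. after a forward-only pass)
#' @keywords internal
#' @export
ad_end_tape <- function() {
  .ad$recording <- FALSE
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av + bv, function(g) { acc(a, g); acc(b, if (length(bv) == 1) sum(g) else g) })
}

ad_sub <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av - bv, function(g) { acc(a, g); acc(b, if (length(bv) == 1) -sum(g) else -g) })
}

ad_mul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av * bv, function(g) {
    acc(a, if (length(av) == 1) sum(g * bv) else g * bv)
    acc(b, if (length(bv) == 1) sum(g * av) else g * av)
  })
}

ad_scale <- function(a, s) {
  ad_node(val(a) * s, function(g) acc(a, g * s))
}

ad_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-val(x)))
  ad_node(y, function(g) acc(x, g * y * (1 - y)))
}

ad_silu <- function(x) {
  xv <- val(x)
  s <- 1 / (1 + exp(-xv))
  ad_node(xv * s, function(g) acc(x, g * s * (1 + xv * (1 - s))))
}

ad_relu <- function(x) {
  xv <- val(x)
  ad_node(pmax(xv, 0), function(g) acc(x, g * (xv > 0)))
}

ad_sum <- function(x) {
  xv <- val(x)
  ad_node(sum(xv), function(g) acc(x, array(g, dim(xv) %||% length(xv))))
}

ad_mean <- function(x) {
  xv <- val(x); n <- length(xv)
  ad_node(sum(xv) / n, function(g) acc(x, array(g / n, dim(xv) %||% length(xv))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_reshape <- function(x, newdim) {
  xv <- val(x); old <- dim(xv) %||% length(xv)
  y <- xv; dim(y) <- newdim
  ad_node(y, function(g) { dim(g) <- old; acc(x, g) })
}

ad_aperm <- function(x, perm) {
  xv <- val(x)
  inv <- order(perm)
  ad_node(aperm(xv, perm), function(g) acc(x, aperm(g, inv)))
}

## ---- matrix / token ops ---------------------------------------------------

ad_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ad_node(av %*% bv, function(g) {
    acc(a, g %*% t(bv))
    acc(b, t(av) %*% g)
  })
}

# x: (n x din), W: (din x dout), b: length dout (or NULL)
ad_linear <- function(x, w, b = NULL) {
  xv <- val(x); wv <- val(w)
  y <- xv %*% wv
  if (!is.null(b)) y <- sweep(y, 2, val(b), "+")
  ad_node(y, function(g) {
    acc(x, g %*% t(wv))
    acc(w, t(xv) %*% g)
    if (!is.null(b)) acc(b, colSums(g))
  })
}

ad_t <- function(x) {
  ad_node(t(val(x)), function(g) acc(x, t(g)))
}

ad_softmax_rows <- function(x) {
  xv <- val(x)
  mx <- xv[cbind(seq_len(nrow(xv)), max.col(xv, ties.method = "first"))]
  e <- exp(xv - mx)
  y <- e / rowSums(e)
  ad_node(y, function(g) acc(x, (g - rowSums(g * y)) * y))
}

ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  xv <- val(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  gv <- val(gamma)
  y <- sweep(xh, 2, gv, "*")
  y <- sweep(y, 2, val(beta), "+")
  d <- ncol(xv)
  ad_node(y, function(g) {
    acc(gamma, colSums(g * xh))
    acc(beta, colSums(g))
    gx <- sweep(g, 2, gv, "*")
    acc(x, (gx - rowMeans(gx) - xh * rowMeans(gx * xh)) * istd)
  })
}

# concatenate token matrices by rows
ad_rbind <- function(lst) {
  vs <- lapply(lst, val)
  ns <- vapply(vs, nrow, 0L)
  ends <- cumsum(ns)
  ad_node(do.call(rbind, vs), function(g) {
    for (i in seq_along(lst)) {
      acc(lst[[i]], g[seq.int(ends[i] - ns[i] + 1L, ends[i]), , drop = FALSE])
    }
  })
}

ad_rows <- function(x, idx) {
  xv <- val(x)
  ad_node(xv[idx, , drop = FALSE], function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    # idx may contain duplicates: aggregate before scatter
    ag <- rowsum(g, group = idx)
    dx[as.integer(rownames(ag)), ] <- ag
    acc(x, dx)
  })
}

ad_cols <- function(x, idx) {
  xv <- val(x)
  ad_node(xv[, idx, drop = FALSE], function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[, idx] <- g
    acc(x, dx)
  })
}

ad_cbind <- function(lst) {
  vs <- lapply(lst, val)
  ns <- vapply(vs, ncol, 0L)
  ends <- cumsum(ns)
  ad_node(do.call(cbind, vs), function(g) {
    for (i in seq_along(lst)) {
      acc(lst[[i]], g[, seq.int(ends[i] - ns[i] + 1L, ends[i]), drop = FALSE])
    }
  })
}

## ---- CHWN feature-map ops -------------------------------------------------

pad_chwn <- function(xv, p) {
  if (p == 0) return(xv)
  d <- dim(xv)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- xv
  xp
}

# weights: (cin, kh, kw, cout); x: (cin, H, W, N); shape-preserving pad = k %/% 2
ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv); kd <- dim(wv)
  if (d[1] != kd[1]) stop("conv2d: input has ", d[1], " channels, kernel expects ", kd[1])
  kh <- kd[2]; kw <- kd[3]; cout <- kd[4]
  if (is.null(pad)) pad <- kh %/% 2L
  xp <- pad_chwn(xv, pad)
  hp <- d[2] + 2 * pad; wp <- d[3] + 2 * pad
  hout <- (hp - kh) %/% stride + 1L
  wout <- (wp - kw) %/% stride + 1L
  m <- hout * wout * d[4]
  K <- array(0, c(kd[1], kh * kw, m))
  i <- 0L
  for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
    i <- i + 1L
    ys <- seq.int(ky, by = stride, length.out = hout)
    xs <- seq.int(kx, by = stride, length.out = wout)
    K[, i, ] <- xp[, ys, xs, , drop = FALSE]
  }
  dim(K) <- c(kd[1] * kh * kw, m)
  wm <- wv; dim(wm) <- c(kd[1] * kh * kw, cout)
  out <- crossprod(wm, K)
  if (!is.null(b)) out <- out + val(b)  # recycles down columns (cout rows)
  dim(out) <- c(cout, hout, wout, d[4])
  ad_node(out, function(g) {
    gm <- g; dim(gm) <- c(cout, m)
    if (!is.null(b)) acc(b, rowSums(gm))
    if (is_node(w)) {
      dw <- tcrossprod(K, gm)  # (cin*kh*kw) x cout
      dim(dw) <- kd
      acc(w, dw)
    }
    if (is_node(x)) {
      dK <- wm %*% gm
      dim(dK) <- c(kd[1], kh * kw, hout, wout, d[4])
      dxp <- array(0, c(kd[1], hp, wp, d[4]))
      i <- 0L
      for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
        i <- i + 1L
        ys <- seq.int(ky, by = stride, length.out = hout)
        xs <- seq.int(kx, by = stride, length.out = wout)
        dki <- dK[, i, , , , drop = FALSE]
        dim(dki) <- c(kd[1], hout, wout, d[4])
        dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + dki
      }
      acc(x, if (pad > 0)
        dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
      else dxp)
    }
  })
}

# per-channel bias on CHWN
ad_bias_c <- function(x, b) {
  xv <- val(x)
  ad_node(xv + val(b), function(g) {
    acc(x, g)
    acc(b, rowSums(matrix(g, dim(xv)[1])))
  })
}

# batch normalization over (H, W, N) per channel; `state` is an environment
# holding running_mean / running_var; training mode uses (and updates with)
# batch statistics, eval mode uses the stored ones.
ad_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  xv <- val(x)
  d <- dim(xv); C <- d[1]; m <- prod(d[-1])
  xm <- matrix(xv, C)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  gv <- val(gamma)
  xh <- (xm - mu) * istd
  y <- xh * (gv) + val(beta)
  dim(y) <- d
  ad_node(y, function(g) {
    gm <- matrix(g, C)
    acc(gamma, rowSums(gm * xh))
    acc(beta, rowSums(gm))
    if (!is_node(x)) return(invisible(NULL))
    gx <- gm * gv
    if (training) {
      dx <- (gx - rowMeans(gx) - xh * rowMeans(gx * xh)) * istd
    } else {
      dx <- gx * istd
    }
    dim(dx) <- d
    acc(x, dx)
  })
}

ad_concat_c <- function(lst) {
  vs <- lapply(lst, val)
  cs <- vapply(vs, function(v) dim(v)[1], 0L)
  ends <- cumsum(cs)
  d1 <- dim(vs[[1]])
  out <- array(0, c(sum(cs), d1[2], d1[3], d1[4]))
  for (i in seq_along(vs)) out[seq.int(ends[i] - cs[i] + 1L, ends[i]), , , ] <- vs[[i]]
  ad_node(out, function(g) {
    for (i in seq_along(lst)) {
      acc(lst[[i]], g[seq.int(ends[i] - cs[i] + 1L, ends[i]), , , , drop = FALSE])
    }
  })
}

ad_slice_c <- function(x, idx) {
  xv <- val(x)
  ad_node(xv[idx, , , , drop = FALSE], function(g) {
    dx <- array(0, dim(xv))
    dx[idx, , , ] <- g
    acc(x, dx)
  })
}

# max pooling, stride 1, shape-preserving (used by the SPPF top block)
ad_maxpool_s1 <- function(x, k) {
  xv <- val(x)
  d <- dim(xv)
  p <- k %/% 2L
  # pad with -Inf so padding never wins the max
  xpad <- array(-Inf, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xpad[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- xv
  best <- array(-Inf, d)
  bestk <- array(0L, d)
  i <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    i <- i + 1L
    sl <- xpad[, seq.int(ky, length.out = d[2]), seq.int(kx, length.out = d[3]), , drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    bestk[upd] <- i
  }
  ad_node(best, function(g) {
    dxp <- array(0, dim(xpad))
    i <- 0L
    for (kx in seq_len(k)) for (ky in seq_len(k)) {
      i <- i + 1L
      ys <- seq.int(ky, length.out = d[2]); xs <- seq.int(kx, length.out = d[3])
      dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + g * (bestk == i)
    }
    acc(x, dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE])
  })
}

# 3x3 average pooling, stride 1, zero padding (divisor always 9, matching the
# all-1/9 convolution it fuses into)
ad_avgpool3_s1 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  xp <- pad_chwn(xv, 1L)
  out <- array(0, d)
  for (kx in 1:3) for (ky in 1:3) {
    out <- out + xp[, seq.int(ky, length.out = d[2]), seq.int(kx, length.out = d[3]), , drop = FALSE]
  }
  out <- out / 9
  ad_node(out, function(g) {
    dxp <- array(0, dim(xp))
    for (kx in 1:3) for (ky in 1:3) {
      ys <- seq.int(ky, length.out = d[2]); xs <- seq.int(kx, length.out = d[3])
      dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + g / 9
    }
    acc(x, dxp[, 1 + seq_len(d[2]), 1 + seq_len(d[3]), , drop = FALSE])
  })
}

# nearest-neighbour 2x upsampling
ad_upsample2 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  yi <- rep(seq_len(d[2]), each = 2)
  xi <- rep(seq_len(d[3]), each = 2)
  ad_node(xv[, yi, xi, , drop = FALSE], function(g) {
    dx <- g[, seq.int(1, 2 * d[2], 2), seq.int(1, 2 * d[3], 2), , drop = FALSE] +
      g[, seq.int(2, 2 * d[2], 2), seq.int(1, 2 * d[3], 2), , drop = FALSE] +
      g[, seq.int(1, 2 * d[2], 2), seq.int(2, 2 * d[3], 2), , drop = FALSE] +
      g[, seq.int(2, 2 * d[2], 2), seq.int(2, 2 * d[3], 2), , drop = FALSE]
    acc(x, dx)
  })
}

# softmax across the channel dimension of a CHWN array
ad_softmax_c <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  xm <- matrix(xv, d[1])
  xm <- sweep(xm, 2, apply(xm, 2, max))
  e <- exp(xm)
  y <- sweep(e, 2, colSums(e), "/")
  yv <- y; dim(yv) <- d
  ad_node(yv, function(g) {
    gm <- matrix(g, d[1])
    dx <- (gm - rep(colSums(gm * y), each = d[1])) * y
    dim(dx) <- d
    acc(x, dx)
  })
}

# rearrange (r^2*K, H, W, N) -> (K, r*H, r*W, N); channel c = k + K*((py-1) + r*(px-1))
ad_pixel_shuffle <- function(x, r) {
  xv <- val(x)
  d <- dim(xv)
  K <- d[1] %/% (r * r)
  stopifnot(K * r * r == d[1])
  x6 <- xv; dim(x6) <- c(K, r, r, d[2], d[3], d[4])
  y <- aperm(x6, c(1, 2, 4, 3, 5, 6))
  dim(y) <- c(K, r * d[2], r * d[3], d[4])
  ad_node(y, function(g) {
    dim(g) <- c(K, r, d[2], r, d[3], d[4])
    dx <- aperm(g, c(1, 2, 4, 3, 5, 6))
    dim(dx) <- d
    acc(x, dx)
  })
}

# extract image n of a CHWN array as a (H*W x C) token matrix, tokens ordered
# x-fastest (t = (y-1)*W + x)
ad_image_tokens <- function(x, n) {
  xv <- val(x)
  d <- dim(xv)
  a <- xv[, , , n]
  dim(a) <- d[1:3]
  tok <- aperm(a, c(3, 2, 1))
  dim(tok) <- c(d[2] * d[3], d[1])
  ad_node(tok, function(g) {
    dim(g) <- c(d[3], d[2], d[1])
    da <- aperm(g, c(3, 2, 1))
    dx <- array(0, d)
    dx[, , , n] <- da
    acc(x, dx)
  })
}

# inverse of ad_image_tokens for a single-image batch
tokens_to_chw <- function(tok, h, w) {
  d <- dim(tok)
  a <- tok
  dim(a) <- c(w, h, d[2])
  out <- aperm(a, c(3, 2, 1))
  dim(out) <- c(d[2], h, w, 1)
  out
}

## ---- optimizer ------------------------------------------------------------

#' AdamW optimizer over a flat list of parameter nodes
#'
#' @param params list of `ad_node` parameters.
#' @param lr learning rate.
#' @param betas length-2 numeric, exponential decay of the moment estimates.
#' @param eps numerical guard.
#' @param weight_decay decoupled weight decay coefficient.
#' @return an optimizer object with a `$step()` method; call after
#'   [ad_backward()], it also clears gradients.
#' @keywords internal
#' @export
adamw <- function(params, lr = 1e-4, betas = c(0.9, 0.999), eps = 1e-8,
                  weight_decay = 1e-4) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$v * 0)  # preserves vector/array shape
  st$u <- lapply(params, function(p) p$v * 0)
  list(
    params = params,
    set_lr = function(new_lr) lr <<- new_lr,
    step = function() {
      st$t <- st$t + 1L
      b1 <- betas[1]; b2 <- betas[2]
      c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
      for (i in seq_along(params)) {
        p <- params[[i]]
        g <- p$g
        if (is.null(g)) next
        st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
        st$u[[i]] <- b2 * st$u[[i]] + (1 - b2) * g^2
        mhat <- st$m[[i]] / c1
        uhat <- st$u[[i]] / c2
        v2 <- p$v - lr * (mhat / (sqrt(uhat) + eps) + weight_decay * p$v)
        attributes(v2) <- attributes(p$v)
        p$v <- v2
        p$g <- NULL
      }
      invisible(NULL)
    },
    zero_grad = function() {
      for (p in params) p$g <- NULL
      invisible(NULL)
    }
  )
}

## ---- misc -----------------------------------------------------------------

# evaluate expr with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## ---- composite detector ops ----------------------------------------------

# zero padding of a CHWN array (backward crops)
ad_pad <- function(x, p) {
  xv <- val(x)
  d <- dim(xv)
  ad_node(pad_chwn(xv, p), function(g) {
    acc(x, g[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE])
  })
}

# CARAFE reassembly: out[c,oy,ox,n] = sum_j kern[j,oy,ox,n] * x[c, sy+dy_j, sx+dx_j, n]
# where (sy,sx) = source cell of output (oy,ox) and (dy_j,dx_j) scans the
# k_up x k_up neighbourhood. `kern` must already be softmax-normalized over
# its first dimension. Border neighbourhoods use edge replication so each
# output stays a convex combination of genuine source values.
ad_carafe_reassemble <- function(x, kern, scale, k_up) {
  xv <- val(x); kv <- val(kern)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  r <- (k_up - 1L) %/% 2L
  kd <- dim(kv)
  stopifnot(kd[1] == k_up * k_up, kd[2] == H * scale, kd[3] == W * scale, kd[4] == N)
  # replicate-padded source
  yi <- c(rep(1L, r), seq_len(H), rep(H, r))
  xi <- c(rep(1L, r), seq_len(W), rep(W, r))
  xp <- xv[, yi, xi, , drop = FALSE]
  sy <- rep(seq_len(H), each = scale)   # source row of each output row
  sx <- rep(seq_len(W), each = scale)
  out <- array(0, c(C, H * scale, W * scale, N))
  j <- 0L
  for (dx in seq.int(-r, r)) for (dy in seq.int(-r, r)) {
    j <- j + 1L
    xs <- xp[, sy + dy + r, sx + dx + r, , drop = FALSE]
    kj <- kv[j, , , , drop = FALSE]
    out <- out + xs * rep(as.vector(kj), each = C)
  }
  ad_node(out, function(g) {
    dk <- array(0, kd)
    dxp <- array(0, dim(xp))
    for (py in seq_len(scale)) for (px in seq_len(scale)) {
      oy <- seq.int(py, H * scale, scale)
      ox <- seq.int(px, W * scale, scale)
      gph <- g[, oy, ox, , drop = FALSE]
      j <- 0L
      for (dx in seq.int(-r, r)) for (dy in seq.int(-r, r)) {
        j <- j + 1L
        ys <- seq_len(H) + dy + r; xsx <- seq_len(W) + dx + r
        xs <- xp[, ys, xsx, , drop = FALSE]
        # d kern
        tmp <- colSums(matrix(gph * xs, C))
        dim(tmp) <- c(1L, H, W, N)
        dk[j, oy, ox, ] <- dk[j, oy, ox, , drop = FALSE] + tmp
        # d x (distinct padded indices within one phase/offset)
        kj <- kv[j, oy, ox, , drop = FALSE]
        dxp[, ys, xsx, ] <- dxp[, ys, xsx, , drop = FALSE] +
          gph * rep(as.vector(kj), each = C)
      }
    }
    acc(kern, dk)
    if (is_node(x)) {
      # fold replicated border rows, then columns, back onto the true extent
      dy2 <- dxp[, r + seq_len(H), , , drop = FALSE]
      for (e in seq_len(r)) {
        dy2[, 1, , ] <- dy2[, 1, , , drop = FALSE] + dxp[, e, , , drop = FALSE]
        dy2[, H, , ] <- dy2[, H, , , drop = FALSE] + dxp[, H + r + e, , , drop = FALSE]
      }
      dxf <- dy2[, , r + seq_len(W), , drop = FALSE]
      for (e in seq_len(r)) {
        dxf[, , 1, ] <- dxf[, , 1, , drop = FALSE] + dy2[, , e, , drop = FALSE]
        dxf[, , W, ] <- dxf[, , W, , drop = FALSE] + dy2[, , W + r + e, , drop = FALSE]
      }
      acc(x, dxf)
    }
  })
}

# FEM channel gate: directional average pooling along H and along W, a shared
# ratio-reduction bottleneck over the concatenated descriptors, a logistic
# per-channel gate g in (0,1), and the residual reinforcement y = x * (1 + g).
# W1: (C/ratio x C), W2: (C x C/ratio); b1, b2 vectors.
ad_fem_gate <- function(x, w1, b1, w2, b2) {
  xv <- val(x)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  if (H == 0 || W == 0) stop("fem: empty feature map")
  dh <- apply(xv, c(1, 2, 4), mean)   # C x H x N (pooled over width)
  dw <- apply(xv, c(1, 3, 4), mean)   # C x W x N (pooled over height)
  Z <- cbind(matrix(dh, C), matrix(dw, C))  # C x (H*N + W*N)
  w1v <- val(w1); w2v <- val(w2)
  U0 <- w1v %*% Z + val(b1)
  U <- pmax(U0, 0)
  V <- w2v %*% U + val(b2)
  # average the per-position logits into one descriptor per (channel, image)
  Vh <- array(V[, seq_len(H * N)], c(nrow(V), H, N))
  Vw <- array(V[, H * N + seq_len(W * N)], c(nrow(V), W, N))
  s <- (apply(Vh, c(1, 3), sum) + apply(Vw, c(1, 3), sum)) / (H + W)  # C x N
  ggate <- 1 / (1 + exp(-s))
  gx <- aperm(array(ggate, c(C, N, H, W)), c(1, 3, 4, 2))
  y <- xv * (1 + gx)
  ad_node(y, function(g) {
    dgate <- apply(g * xv, c(1, 4), sum)          # C x N
    ds <- dgate * ggate * (1 - ggate) / (H + W)   # C x N
    dVh <- array(0, dim(Vh)); dVw <- array(0, dim(Vw))
    for (n in seq_len(N)) { dVh[, , n] <- ds[, n]; dVw[, , n] <- ds[, n] }
    dV <- cbind(matrix(dVh, nrow(V)), matrix(dVw, nrow(V)))
    acc(w2, dV %*% t(U)); acc(b2, rowSums(dV))
    dU <- (t(w2v) %*% dV) * (U0 > 0)
    acc(w1, dU %*% t(Z)); acc(b1, rowSums(dU))
    if (is_node(x)) {
      dZ <- t(w1v) %*% dU
      ddh <- array(dZ[, seq_len(H * N)], c(C, H, N)) / W
      ddw <- array(dZ[, H * N + seq_len(W * N)], c(C, W, N)) / H
      dx <- g * (1 + gx) +
        aperm(array(ddh, c(C, H, N, W)), c(1, 2, 4, 3)) +
        aperm(array(ddw, c(C, W, N, H)), c(1, 4, 2, 3))
      acc(x, dx)
    }
  })
}

# Bilinear sampling of rows of a (H*W x d) token matrix at normalized
# coordinates (P x 2 matrix of (x, y) in [0,1], pixel centers at (i-0.5)/W).
# Tokens are ordered x-fastest. Out-of-range samples clamp to the border.
# Gradients flow to both the value matrix and the coordinates.
ad_bilinear_rows <- function(v, coords, h, w) {
  vv <- val(v); cv <- val(coords)
  gx <- cv[, 1] * w - 0.5
  gy <- cv[, 2] * h - 0.5
  x0 <- floor(gx); y0 <- floor(gy)
  wx <- gx - x0; wy <- gy - y0
  cx0 <- pmin(pmax(x0, 0), w - 1); cx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  cy0 <- pmin(pmax(y0, 0), h - 1); cy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  i00 <- cy0 * w + cx0 + 1; i01 <- cy0 * w + cx1 + 1
  i10 <- cy1 * w + cx0 + 1; i11 <- cy1 * w + cx1 + 1
  v00 <- vv[i00, , drop = FALSE]; v01 <- vv[i01, , drop = FALSE]
  v10 <- vv[i10, , drop = FALSE]; v11 <- vv[i11, , drop = FALSE]
  out <- v00 * ((1 - wx) * (1 - wy)) + v01 * (wx * (1 - wy)) +
    v10 * ((1 - wx) * wy) + v11 * (wx * wy)
  ad_node(out, function(g) {
    if (is_node(v)) {
      dv <- matrix(0, nrow(vv), ncol(vv))
      idx <- c(i00, i01, i10, i11)
      gg <- rbind(g * ((1 - wx) * (1 - wy)), g * (wx * (1 - wy)),
                  g * ((1 - wx) * wy), g * (wx * wy))
      ag <- rowsum(gg, group = idx)
      dv[as.integer(rownames(ag)), ] <- ag
      acc(v, dv)
    }
    if (is_node(coords)) {
      dwx <- rowSums(g * (-v00 * (1 - wy) + v01 * (1 - wy) - v10 * wy + v11 * wy))
      dwy <- rowSums(g * (-v00 * (1 - wx) - v01 * wx + v10 * (1 - wx) + v11 * wx))
      acc(coords, cbind(dwx * w, dwy * h))
    }
  })
}

ad_log <- function(x, eps = 1e-12) {
  xv <- pmax(val(x), eps)
  ad_node(log(xv), function(g) acc(x, g / xv))
}

ad_abs <- function(x) {
  xv <- val(x)
  ad_node(abs(xv), function(g) acc(x, g * sign(xv)))
}

ad_pow <- function(x, k) {
  xv <- val(x)
  ad_node(xv^k, function(g) acc(x, g * k * xv^(k - 1)))
}

# assemble N per-image (H*W x C) token matrices back into a CHWN array
ad_stack_tokens <- function(lst, h, w) {
  n <- length(lst)
  C <- ncol(val(lst[[1]]))
  out <- array(0, c(C, h, w, n))
  for (i in seq_len(n)) out[, , , i] <- tokens_to_chw(val(lst[[i]]), h, w)
  ad_node(out, function(g) {
    for (i in seq_len(n)) {
      gi <- g[, , , i]
      dim(gi) <- c(C, h, w)
      tok <- aperm(gi, c(3, 2, 1))
      dim(tok) <- c(h * w, C)
      acc(lst[[i]], tok)
    }
  })
}

# fused multi-head scaled-dot-product attention (one tape node). q, k, v are
# token-matrix nodes; the projection weights/biases are parameter nodes.
ad_mha_fused <- function(q, k, v, wq, bq, wk, bk, wv, bv, wo, bo, nhead) {
  qv <- val(q); kv <- val(k); vv <- val(v)
  wqv <- val(wq); wkv <- val(wk); wvv <- val(wv); wov <- val(wo)
  d <- ncol(wqv); dh <- d %/% nhead
  Q <- qv %*% wqv; Q <- Q + rep(val(bq), each = nrow(Q))
  K <- kv %*% wkv; K <- K + rep(val(bk), each = nrow(K))
  V <- vv %*% wvv; V <- V + rep(val(bv), each = nrow(V))
  sc <- 1 / sqrt(dh)
  A <- vector("list", nhead)
  O <- matrix(0, nrow(Q), d)
  for (h in seq_len(nhead)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * sc
    mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
    E <- exp(S - mx)
    A[[h]] <- E / rowSums(E)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% wov
  out <- out + rep(val(bo), each = nrow(out))
  ad_node(out, function(g) {
    acc(wo, crossprod(O, g))
    acc(bo, colSums(g))
    dO <- tcrossprod(g, wov)
    dQ <- matrix(0, nrow(Q), d); dK <- matrix(0, nrow(K), d); dV <- matrix(0, nrow(V), d)
    for (h in seq_len(nhead)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      Ah <- A[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(Ah, dOh)
      dS <- (dA - rowSums(dA * Ah)) * Ah * sc
      dQ[, idx] <- dS %*% K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, Q[, idx, drop = FALSE])
    }
    acc(wq, crossprod(qv, dQ)); acc(bq, colSums(dQ))
    acc(wk, crossprod(kv, dK)); acc(bk, colSums(dK))
    acc(wv, crossprod(vv, dV)); acc(bv, colSums(dV))
    if (is_node(q)) acc(q, tcrossprod(dQ, wqv))
    if (is_node(k)) acc(k, tcrossprod(dK, wkv))
    if (is_node(v)) acc(v, tcrossprod(dV, wvv))
  })
}
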