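# Minimal LSTM/dense stack with full backpropagation-through-time, written
# directly in R matrix algebra. Layers operate on a batch of sliding
# windows: activations are (batch x units) matrices per timestep. The output
# head is linear and reads the last timestep of the top layer.

sigm <- function(x) stats::plogis(x)

# scaled uniform init, seeded by the caller
init_mat <- function(nr, nc) {
  r <- 1 / sqrt(max(nc, 1))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

lstm_layer_new <- function(input_size, units) {
  list(type = "lstm", input_size = input_size, units = units,
       # gate order within the stacked 4u rows: input, forget, output, cand
       W = init_mat(4 * units, input_size),
       U = init_mat(4 * units, units),
       b = matrix(0, 1, 4 * units))
}

dense_layer_new <- function(input_size, units, activation = "tanh") {
  list(type = "dense", input_size = input_size, units = units,
       activation = activation,
       W = init_mat(units, input_size),
       b = matrix(0, 1, units))
}

slice4 <- function(m, units, k) m[, ((k - 1) * units + 1):(k * units), drop = FALSE]

# forward one layer over a list of (batch x input) matrices; returns
# activations plus caches needed for the backward pass
layer_forward <- function(layer, xs) {
  T_ <- length(xs)
  batch <- nrow(xs[[1]])
  if (layer$type == "dense") {
    hs <- vector("list", T_)
    pre <- vector("list", T_)
    for (t in seq_len(T_)) {
      a <- xs[[t]] %*% t(layer$W) + matrix(layer$b, batch, layer$units,
                                           byrow = TRUE)
      pre[[t]] <- a
      hs[[t]] <- if (layer$activation == "tanh") tanh(a) else a
    }
    return(list(hs = hs, cache = list(xs = xs, pre = pre)))
  }
  u <- layer$units
  h <- matrix(0, batch, u)
  c_ <- matrix(0, batch, u)
  hs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- xs[[t]] %*% t(layer$W) + h %*% t(layer$U) +
      matrix(layer$b, batch, 4 * u, byrow = TRUE)
    ig <- sigm(slice4(z, u, 1))
    fg <- sigm(slice4(z, u, 2))
    og <- sigm(slice4(z, u, 3))
    gg <- tanh(slice4(z, u, 4))
    c_prev <- c_
    c_ <- fg * c_prev + ig * gg
    tc <- tanh(c_)
    h_prev <- h
    h <- og * tc
    hs[[t]] <- h
    cache[[t]] <- list(x = xs[[t]], ig = ig, fg = fg, og = og, gg = gg,
                       c_prev = c_prev, c_ = c_, tc = tc, h_prev = h_prev)
  }
  list(hs = hs, cache = cache)
}

# backward one layer; dh_seq is a list of (batch x units) gradients (may
# contain NULLs meaning zero). Returns gradient w.r.t. inputs and weight
# gradients (summed over the batch).
layer_backward <- function(layer, fw, dh_seq) {
  T_ <- length(dh_seq)
  if (layer$type == "dense") {
    dW <- layer$W * 0
    db <- layer$b * 0
    dxs <- vector("list", T_)
    for (t in seq_len(T_)) {
      dh <- dh_seq[[t]]
      if (is.null(dh)) next
      da <- if (layer$activation == "tanh") {
        dh * (1 - tanh(fw$cache$pre[[t]])^2)
      } else dh
      dW <- dW + t(da) %*% fw$cache$xs[[t]]
      db <- db + colSums(da)
      dxs[[t]] <- da %*% layer$W
    }
    return(list(dxs = dxs, grads = list(W = dW, b = db)))
  }
  u <- layer$units
  dW <- layer$W * 0
  dU <- layer$U * 0
  db <- layer$b * 0
  dxs <- vector("list", T_)
  dh_next <- NULL
  dc_next <- NULL
  for (t in rev(seq_len(T_))) {
    cc <- fw$cache[[t]]
    dh <- dh_seq[[t]]
    if (is.null(dh)) dh <- 0
    if (!is.null(dh_next)) dh <- dh + dh_next
    if (identical(dh, 0)) next
    do <- dh * cc$tc
    dct <- dh * cc$og * (1 - cc$tc^2)
    if (!is.null(dc_next)) dct <- dct + dc_next
    di <- dct * cc$gg
    df <- dct * cc$c_prev
    dg <- dct * cc$ig
    dc_next <- dct * cc$fg
    da <- cbind(di * cc$ig * (1 - cc$ig),
                df * cc$fg * (1 - cc$fg),
                do * cc$og * (1 - cc$og),
                dg * (1 - cc$gg^2))
    dW <- dW + t(da) %*% cc$x
    dU <- dU + t(da) %*% cc$h_prev
    db <- db + colSums(da)
    dxs[[t]] <- da %*% layer$W
    dh_next <- da %*% layer$U
  }
  list(dxs = dxs, grads = list(W = dW, U = dU, b = db))
}

# build the layer stack for a pattern string like "LDL"
build_stack <- function(layer_pattern, hidden_units) {
  chars <- strsplit(layer_pattern, "")[[1]]
  if (!length(chars) %in% c(3L, 4L) || !all(chars %in% c("L", "D"))) {
    stop("`layer_pattern` must be a string of 3-4 characters over {L, D}",
         call. = FALSE)
  }
  layers <- vector("list", length(chars))
  in_size <- 1L
  for (k in seq_along(chars)) {
    layers[[k]] <- if (chars[k] == "L") {
      lstm_layer_new(in_size, hidden_units)
    } else {
      dense_layer_new(in_size, hidden_units, "tanh")
    }
    in_size <- hidden_units
  }
  # linear head: last layer's final timestep -> single value
  head <- dense_layer_new(in_size, 1L, "linear")
  list(layers = layers, head = head)
}

stack_forward <- function(stack, xs) {
  fws <- vector("list", length(stack$layers))
  cur <- xs
  for (k in seq_along(stack$layers)) {
    fws[[k]] <- layer_forward(stack$layers[[k]], cur)
    cur <- fws[[k]]$hs
  }
  last_h <- cur[[length(cur)]]
  pred <- last_h %*% t(stack$head$W) +
    matrix(stack$head$b, nrow(last_h), 1, byrow = TRUE)
  list(fws = fws, last_h = last_h, pred = drop(pred), T_ = length(xs))
}

# gradient of mean-squared-error loss through the whole stack
stack_backward <- function(stack, fw, dpred) {
  batch <- length(dpred)
  dpred <- matrix(dpred, batch, 1)
  gW_head <- t(dpred) %*% fw$last_h
  gb_head <- colSums(dpred)
  dh_last <- dpred %*% stack$head$W
  grads <- vector("list", length(stack$layers))
  dh_seq <- vector("list", fw$T_)
  dh_seq[[fw$T_]] <- dh_last
  for (k in rev(seq_along(stack$layers))) {
    bw <- layer_backward(stack$layers[[k]], fw$fws[[k]], dh_seq)
    grads[[k]] <- bw$grads
    dh_seq <- bw$dxs
  }
  list(layer_grads = grads, head_grads = list(W = gW_head, b = gb_head))
}

# global gradient-norm clipping at `clip`
clip_grads <- function(all_grads, clip) {
  flat <- unlist(all_grads, use.names = FALSE)
  nrm <- sqrt(sum(flat^2))
  if (is.finite(nrm) && nrm > clip) {
    all_grads <- rapply(all_grads, function(g) g * (clip / nrm),
                        how = "replace")
  }
  all_grads
}

# one SGD+momentum update; velocity carried in `vel` (same shape as grads)
sgd_update <- function(stack, grads, vel, lr, momentum) {
  upd <- function(w, g, v) {
    v2 <- momentum * v - lr * g
    list(w = w + v2, v = v2)
  }
  for (k in seq_along(stack$layers)) {
    for (nm in names(grads$layer_grads[[k]])) {
      r <- upd(stack$layers[[k]][[nm]], grads$layer_grads[[k]][[nm]],
               vel$layers[[k]][[nm]])
      stack$layers[[k]][[nm]] <- r$w
      vel$layers[[k]][[nm]] <- r$v
    }
  }
  for (nm in names(grads$head_grads)) {
    r <- upd(stack$head[[nm]], grads$head_grads[[nm]], vel$head[[nm]])
    stack$head[[nm]] <- r$w
    vel$head[[nm]] <- r$v
  }
  list(stack = stack, vel = vel)
}

zero_velocity <- function(stack) {
  list(layers = lapply(stack$layers, function(l) {
    out <- list(W = l$W * 0, b = l$b * 0)
    if (l$type == "lstm") out$U <- l$U * 0
    out
  }),
  head = list(W = stack$head$W * 0, b = stack$head$b * 0))
}

# windows matrix (n_samples x window) -> list of per-timestep column matrices
windows_to_xs <- function(win) {
  lapply(seq_len(ncol(win)), function(t) win[, t, drop = FALSE])
}

stack_predict <- function(stack, win) {
  stack_forward(stack, windows_to_xs(win))$pred
}
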