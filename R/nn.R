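# Internal dense-matrix engine for the masked network. Every weight
# matrix carries a binary mask; positions outside the mask are held at
# exactly zero (never updated), and frozen identity skip-through entries
# are held at exactly one. Networks here are small (tens of units), so a
# plain base-R implementation is both fast enough and easy to audit.

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(z, h) 1 - h^2),
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, h) (z > 0) * 1),
         identity = list(f = identity, df = function(z, h) 1),
         stopf("unknown activation '%s'", name))
}

glorot_init <- function(mask, trainable) {
  W <- matrix(0, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  for (j in seq_len(ncol(mask))) {
    tr <- which(trainable[, j])
    if (length(tr) > 0) {
      s <- sqrt(6 / (length(tr) + 1))
      W[tr, j] <- stats::runif(length(tr), -s, s)
    }
  }
  W[mask == 1 & !trainable] <- 1  # frozen identity channels
  W
}

# Forward pass through the VNN trunk + head.
# X: n x p gene matrix (columns in spec$feature_order); C: n x q clinical.
# dropout_masks: NULL (eval) or list(vnn = list per layer, head = matrix).
# clamp: NULL or list(off = character pathway ids, acts = list per layer
#   of named numeric vectors of unit values to substitute for the off
#   pathways' units once computed).
# Returns list(risk, acts) where acts[[l]] is the layer-l output and
# acts$root / acts$hidden support backprop.
nn_forward <- function(model, X, C, dropout_masks = NULL, clamp = NULL,
                       keep = FALSE) {
  spec <- model$spec
  act <- act_fun(model$activation)
  H <- X
  store <- if (keep) vector("list", spec$n_layers) else NULL
  for (l in seq_len(spec$n_layers)) {
    ls <- spec$layers[[l]]
    # project through the mask: masked-out positions are structurally
    # absent, whatever value the dense storage holds
    W <- model$vnn[[l]]$W * ls$mask
    Z <- H %*% W + matrix(model$vnn[[l]]$b, nrow(H), length(ls$out_names),
                          byrow = TRUE)
    Hn <- Z
    ip <- ls$is_pathway
    if (any(ip)) Hn[, ip] <- act$f(Z[, ip, drop = FALSE])
    if (!is.null(dropout_masks) && any(ip)) {
      Hn[, ip] <- Hn[, ip, drop = FALSE] * dropout_masks$vnn[[l]]
    }
    if (!is.null(clamp) && length(clamp$off) > 0) {
      sub <- clamp$acts[[l]]
      hit <- intersect(names(sub), ls$out_names)
      if (length(hit) > 0) {
        Hn[, hit] <- matrix(sub[hit], nrow(Hn), length(hit), byrow = TRUE)
      }
    }
    if (keep) store[[l]] <- list(Hin = H, Z = Z, Hout = Hn)
    H <- Hn
  }
  root <- H
  if (spec$root_mode == "dense") {
    root <- root %*% model$root$W +
      matrix(model$root$b, nrow(root), spec$root_width, byrow = TRUE)
  }
  R <- cbind(root, C)
  Z1 <- R %*% model$head$W1 + matrix(model$head$b1, nrow(R),
                                     model$head_width, byrow = TRUE)
  A1 <- act$f(Z1)
  if (!is.null(dropout_masks)) A1 <- A1 * dropout_masks$head
  risk <- drop(A1 %*% model$head$W2 + model$head$b2)
  if (!keep) return(list(risk = risk))
  list(risk = risk,
       acts = list(vnn = store, rootin = H, R = R, Z1 = Z1, A1 = A1))
}

# Backward pass; drisk is dLoss/drisk (length n). Returns gradients with
# the same shapes as the parameters; masked-out positions are exactly 0.
nn_backward <- function(model, fw, X, C, drisk, dropout_masks = NULL) {
  spec <- model$spec
  act <- act_fun(model$activation)
  n <- length(drisk)
  dA1 <- matrix(drisk, n, 1) %*% t(model$head$W2)
  gW2 <- t(fw$acts$A1) %*% matrix(drisk, n, 1)
  gb2 <- sum(drisk)
  if (!is.null(dropout_masks)) dA1 <- dA1 * dropout_masks$head
  dZ1 <- dA1 * act$df(fw$acts$Z1, act$f(fw$acts$Z1))
  gW1 <- t(fw$acts$R) %*% dZ1
  gb1 <- colSums(dZ1)
  dR <- dZ1 %*% t(model$head$W1)
  rw <- if (spec$root_mode == "dense") spec$root_width else
    length(spec$root_units)
  droot <- dR[, seq_len(rw), drop = FALSE]
  groot <- NULL
  if (spec$root_mode == "dense") {
    groot <- list(W = t(fw$acts$rootin) %*% droot, b = colSums(droot))
    droot <- droot %*% t(model$root$W)
  }
  dH <- droot
  gvnn <- vector("list", spec$n_layers)
  for (l in rev(seq_len(spec$n_layers))) {
    ls <- spec$layers[[l]]
    st <- fw$acts$vnn[[l]]
    ip <- ls$is_pathway
    dZ <- dH
    if (!is.null(dropout_masks) && any(ip)) {
      dZ[, ip] <- dZ[, ip, drop = FALSE] * dropout_masks$vnn[[l]]
    }
    if (any(ip)) {
      h <- st$Hout[, ip, drop = FALSE]
      if (!is.null(dropout_masks)) {
        # recover pre-dropout activation for the derivative
        h <- act$f(st$Z[, ip, drop = FALSE])
      }
      dZ[, ip] <- dZ[, ip, drop = FALSE] * act$df(st$Z[, ip, drop = FALSE], h)
    }
    gW <- t(st$Hin) %*% dZ
    gW[!ls$trainable] <- 0
    gb <- colSums(dZ)
    gb[!ip] <- 0
    gvnn[[l]] <- list(W = gW, b = gb)
    dH <- dZ %*% t(model$vnn[[l]]$W * ls$mask)
  }
  list(vnn = gvnn, root = groot,
       head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

new_adamw_state <- function(model) {
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  shape <- function(p) lapply(p, zero_like)
  st <- list(t = 0,
             m = list(vnn = lapply(model$vnn, shape),
                      head = shape(model$head)),
             v = list(vnn = lapply(model$vnn, shape),
                      head = shape(model$head)))
  if (!is.null(model$root)) {
    st$m$root <- shape(model$root)
    st$v$root <- shape(model$root)
  }
  st
}

# One AdamW step. Decoupled weight decay applied to weight matrices only
# (not biases), and only at trainable positions.
adamw_step <- function(model, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, decay_mask) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    p <- p - step
    if (!is.null(decay_mask)) p <- p - lr * weight_decay * p * decay_mask
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(model$vnn)) {
    tr <- model$spec$layers[[l]]$trainable
    gW <- grads$vnn[[l]]$W
    u <- upd(model$vnn[[l]]$W, gW, state$m$vnn[[l]]$W, state$v$vnn[[l]]$W, tr)
    # restore structural zeros/frozen entries exactly
    u$p[!tr] <- model$spec$layers[[l]]$mask[!tr]
    model$vnn[[l]]$W <- u$p
    state$m$vnn[[l]]$W <- u$m; state$v$vnn[[l]]$W <- u$v
    ub <- upd(model$vnn[[l]]$b, grads$vnn[[l]]$b,
              state$m$vnn[[l]]$b, state$v$vnn[[l]]$b, NULL)
    ub$p[!model$spec$layers[[l]]$is_pathway] <- 0
    model$vnn[[l]]$b <- ub$p
    state$m$vnn[[l]]$b <- ub$m; state$v$vnn[[l]]$b <- ub$v
  }
  if (!is.null(model$root)) {
    for (nm in c("W", "b")) {
      dm <- if (nm == "W") 1 else NULL
      u <- upd(model$root[[nm]], grads$root[[nm]],
               state$m$root[[nm]], state$v$root[[nm]], dm)
      model$root[[nm]] <- u$p
      state$m$root[[nm]] <- u$m; state$v$root[[nm]] <- u$v
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    dm <- if (nm %in% c("W1", "W2")) 1 else NULL
    u <- upd(model$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]], dm)
    model$head[[nm]] <- u$p
    state$m$head[[nm]] <- u$m; state$v$head[[nm]] <- u$v
  }
  list(model = model, state = state)
}

draw_dropout_masks <- function(model, n) {
  p <- model$dropout
  if (p <= 0) return(NULL)
  vnn <- lapply(model$spec$layers, function(ls) {
    k <- sum(ls$is_pathway)
    matrix(stats::rbinom(n * k, 1, 1 - p) / (1 - p), n, k)
  })
  head <- matrix(stats::rbinom(n * model$head_width, 1, 1 - p) / (1 - p),
                 n, model$head_width)
  list(vnn = vnn, head = head)
}
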