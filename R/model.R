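# Full model: wiring of the contrastive block, the three-view encoder,
# attention fusion, ZINB reconstruction and the spatial regularizer into
# one differentiable objective, with a hand-derived backward pass and an
# Adam optimizer. Parameters live in a nested list whose numeric leaves
# are flattened for optimization and finite-difference checking.

# ---- parameter tree <-> flat vector -------------------------------------

flatten_numeric <- function(x) {
  if (is.list(x)) return(unlist(lapply(x, flatten_numeric),
                                use.names = FALSE))
  if (is.numeric(x)) return(as.vector(x))
  numeric(0)
}

# write `flat` back into the numeric leaves of `tree` (same traversal
# order as flatten_numeric), preserving dims
inject_numeric <- function(tree, flat, pos = 1L) {
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      r <- inject_numeric(tree[[i]], flat, pos)
      tree[[i]] <- r$tree
      pos <- r$pos
    }
    return(list(tree = tree, pos = pos))
  }
  if (is.numeric(tree)) {
    len <- length(tree)
    new <- flat[pos:(pos + len - 1L)]
    if (!is.null(dim(tree))) dim(new) <- dim(tree)
    return(list(tree = new, pos = pos + len))
  }
  list(tree = tree, pos = pos)
}

set_params_flat <- function(params, flat) inject_numeric(params, flat)$tree

# ---- model construction --------------------------------------------------

# default architecture hyper-parameters
default_arch <- function() {
  list(dims_contrastive = c(128L, 64L),
       dims_view = c(64L, 64L),
       att_h = 32L, att_h2 = 16L)
}

# initialize all trainable parameters for a given wiring
init_model_params <- function(m_genes, cfg, seed = 0L) {
  arch <- cfg$arch
  d_latent <- arch$dims_contrastive[length(arch$dims_contrastive)]
  d_in_f <- if (cfg$no_cl) m_genes
  else if (cfg$feature_input == "latent") d_latent else m_genes
  p <- list()
  if (!cfg$no_cl)
    p$con <- init_contrastive_params(m_genes, arch$dims_contrastive,
                                     seed = seed)
  mv <- list()
  if (!cfg$no_knn)
    mv$s <- init_stack(c(m_genes, arch$dims_view), "relu", seed + 10L)
  if (!cfg$no_radius)
    mv$s_a <- init_stack(c(m_genes, arch$dims_view), "relu", seed + 11L)
  mv$f <- init_stack(c(d_in_f, arch$dims_view), "relu", seed + 12L)
  mv$c <- init_stack(c(d_in_f, arch$dims_view), "relu", seed + 13L)
  p$mv <- mv
  d <- arch$dims_view[length(arch$dims_view)]
  p$att <- init_attention_params(d, arch$att_h, arch$att_h2,
                                 seed = seed + 20L)
  p$zinb <- init_zinb_params(d, m_genes, seed = seed + 30L)
  p
}

# generic anchored Gram-consistency over >= 2 branch embeddings
consistency_list_fb <- function(Zs) {
  rns <- lapply(Zs, function(Z) row_normalize(as.matrix(Z)))
  Gs <- lapply(rns, function(r) tcrossprod(r$Zt))
  nb <- length(Zs)
  Ds <- lapply(2:nb, function(j) Gs[[1L]] - Gs[[j]])
  loss <- sum(vapply(Ds, function(D) sum(D^2), numeric(1)))
  grad <- function() {
    dG <- vector("list", nb)
    dG[[1L]] <- 2 * Reduce(`+`, Ds)
    for (j in 2:nb) dG[[j]] <- -2 * Ds[[j - 1L]]
    lapply(seq_len(nb), function(j)
      row_normalize_backward(2 * dG[[j]] %*% rns[[j]]$Zt, Zs[[j]], rns[[j]]))
  }
  list(loss = loss, grad = grad)
}

# ---- forward -------------------------------------------------------------

# data: list(X, Xc, counts, A_knn, A_radius, A_f, reg_spec)
# cfg: list(alpha, cl_form, lambda, feature_input, no_cl, no_wfa, no_knn,
#           no_radius, arch)
model_forward <- function(params, data, cfg) {
  lam <- cfg$lambda
  # contrastive block
  if (!cfg$no_cl) {
    cfw <- contrastive_forward(data$X, data$Xc, data$A_f, params$con,
                               cfg$alpha, cfg$cl_form,
                               need_recon_aug = FALSE)
    L_com <- cfw$L_com
    Fin <- if (cfg$feature_input == "latent") cfw$h0 else data$Xc
  } else {
    cfw <- NULL
    L_com <- 0
    Fin <- data$X
  }
  # spatial views
  sp_ops <- list()
  if (!cfg$no_knn) sp_ops$knn <- data$A_knn
  if (!cfg$no_radius) sp_ops$radius <- data$A_radius
  sp_fw <- list(); sp_Z <- list()
  sp_stacks <- c(if (!cfg$no_knn) "s", if (!cfg$no_radius) "s_a")
  for (i in seq_along(sp_ops)) {
    st <- params$mv[[sp_stacks[i]]]
    f <- stack_forward(data$X, sp_ops[[i]], st)
    sp_fw[[i]] <- f
    sp_Z[[i]] <- f$H[[length(f$H)]]
  }
  Zs_joint <- Reduce(`+`, sp_Z) / length(sp_Z)
  # feature view
  ff <- stack_forward(Fin, data$A_f, params$mv$f)
  Zf <- ff$H[[length(ff$H)]]
  # co-convolution (shared weights) over spatial graphs + feature graph
  co_ops <- c(sp_ops, list(feat = data$A_f))
  co_fw <- list(); co_Z <- list()
  for (i in seq_along(co_ops)) {
    f <- stack_forward(Fin, co_ops[[i]], params$mv$c)
    co_fw[[i]] <- f
    co_Z[[i]] <- f$H[[length(f$H)]]
  }
  Zc_joint <- Reduce(`+`, co_Z) / length(co_Z)
  cons <- consistency_list_fb(co_Z)
  L_con <- cons$loss
  # attention fusion
  att_fw <- attention_forward(list(Zs_joint, Zc_joint, Zf), params$att,
                              equal_weights = cfg$no_wfa)
  Z <- att_fw$Z
  # ZINB reconstruction
  zd <- zinb_decode_forward(Z, params$zinb)
  znll <- zinb_nll_fb(data$counts, zd$pi, zd$mu, zd$theta)
  L_zinb <- znll$loss
  # spatial regularization on the fused embedding
  rg <- spatial_reg_fb(Z, data$reg_spec)
  L_reg <- rg$loss
  total <- total_loss(L_zinb, L_com, L_con, L_reg, lam)
  list(total = total,
       terms = c(zinb = L_zinb, com = L_com, con = L_con, reg = L_reg),
       Z = Z, att_weights = att_fw$Wt,
       cache = list(cfw = cfw, Fin = Fin, sp_ops = sp_ops, sp_fw = sp_fw,
                    sp_Z = sp_Z, sp_stacks = sp_stacks, ff = ff, Zf = Zf,
                    co_ops = co_ops, co_fw = co_fw, co_Z = co_Z,
                    cons = cons, att_fw = att_fw, zd = zd, znll = znll,
                    rg = rg))
}

# ---- backward ------------------------------------------------------------

model_backward <- function(fw, params, data, cfg) {
  lam <- cfg$lambda
  ca <- fw$cache
  Z <- fw$Z
  # gradients flowing into the fused embedding
  g_nll <- ca$znll$grad()
  zb <- zinb_decode_backward(ca$zd, Z, params$zinb,
                             lam[1] * g_nll$d_pi, lam[1] * g_nll$d_mu,
                             lam[1] * g_nll$d_theta)
  dZ <- zb$dZ + lam[4] * ca$rg$grad()
  # attention
  ab <- attention_backward(ca$att_fw, params$att, dZ)
  g_att <- if (is.null(ab$dParams)) {
    list(W1 = params$att$W1 * 0, b1 = params$att$b1 * 0,
         W2 = params$att$W2 * 0, b2 = params$att$b2 * 0,
         v = params$att$v * 0)
  } else ab$dParams
  d_Fin <- ca$Fin * 0
  g_mv <- list()
  # spatial views
  np <- length(ca$sp_Z)
  for (i in seq_along(ca$sp_Z)) {
    bk <- stack_backward(ca$sp_fw[[i]], ca$sp_ops[[i]],
                         params$mv[[ca$sp_stacks[i]]], ab$dViews[[1L]] / np)
    g_mv[[ca$sp_stacks[i]]] <- list(W = bk$dW, b = bk$db)
  }
  # feature view
  bk_f <- stack_backward(ca$ff, data$A_f, params$mv$f, ab$dViews[[3L]])
  g_mv$f <- list(W = bk_f$dW, b = bk_f$db)
  d_Fin <- d_Fin + bk_f$dH0
  # co-convolution branches (shared weights accumulate)
  nb <- length(ca$co_Z)
  d_cons <- ca$cons$grad()
  g_c <- zero_like_stack(params$mv$c)
  for (i in seq_len(nb)) {
    dZco <- ab$dViews[[2L]] / nb + lam[3] * d_cons[[i]]
    bk <- stack_backward(ca$co_fw[[i]], ca$co_ops[[i]], params$mv$c, dZco)
    g_c <- add_stack_grads(g_c, bk[c("dW", "db")])
    d_Fin <- d_Fin + bk$dH0
  }
  g_mv$c <- list(W = g_c$dW, b = g_c$db)
  grads <- list()
  # contrastive block
  if (!cfg$no_cl) {
    d_h0_extra <- if (cfg$feature_input == "latent") d_Fin else NULL
    cb <- contrastive_backward(ca$cfw, data$X, data$Xc, data$A_f,
                               params$con, scale = lam[2],
                               d_h0_extra = d_h0_extra)
    grads$con <- list(
      enc0 = list(W = cb$enc0$dW, b = cb$enc0$db),
      enc1 = list(W = cb$enc1$dW, b = cb$enc1$db),
      dec0 = list(W = cb$dec0$dW, b = cb$dec0$db),
      dec1 = list(W = cb$dec1$dW, b = cb$dec1$db))
  }
  # order must mirror init_model_params for flattening
  grads$mv <- g_mv[names(params$mv)]
  grads$att <- g_att
  grads$zinb <- zb$dParams
  grads
}

# scalar objective as a function of the flat parameter vector (used by the
# finite-difference oracle in the tests)
model_loss_flat <- function(flat, params, data, cfg) {
  p <- set_params_flat(params, flat)
  model_forward(p, data, cfg)$total
}

# central finite-difference gradient of f at x
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr = 1e-3, weight_decay = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- grad + weight_decay * theta
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
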