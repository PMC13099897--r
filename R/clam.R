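# Single-branch clustering-constrained attention MIL with gated
# attention, a GELU two-layer classifier head, module-wise dropout, and
# a bag + instance composite loss. Gradients are hand-derived
# reverse-mode and checked against finite differences in the tests.

#' CLAM-style model configuration
#'
#' Defaults follow the published training settings: 1024-dim input
#' embeddings, 512-dim instance encoder, 384-dim gated-attention space,
#' 512 to 256 classifier reduction, dropout 0.4 applied independently to
#' the encoder, attention and classifier modules, instance-clustering
#' sample size 8, and equal bag/instance loss weighting.
#'
#' @param input_dim Instance feature dimension D.
#' @param encoder_hidden Instance-encoder width.
#' @param attn_hidden Gated-attention hidden width.
#' @param cls_hidden Classifier hidden width.
#' @param n_classes Number of risk tiers.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param k_sample Instances sampled from each attention extreme for the
#'   clustering loss.
#' @param bag_weight Weight of the bag loss in the composite objective.
#' @return A `clam_config` list.
#' @export
clam_config <- function(input_dim = 1024L, encoder_hidden = 512L,
                        attn_hidden = 384L, cls_hidden = 256L,
                        n_classes = 3L, dropout = 0.4, k_sample = 8L,
                        bag_weight = 0.5) {
  stopifnot(input_dim > 0, encoder_hidden > 0, attn_hidden > 0,
            cls_hidden > 0, dropout >= 0, dropout < 1,
            bag_weight >= 0, bag_weight <= 1)
  structure(list(input_dim = as.integer(input_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 attn_hidden = as.integer(attn_hidden),
                 cls_hidden = as.integer(cls_hidden),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 k_sample = as.integer(k_sample), bag_weight = bag_weight),
            class = "clam_config")
}

#' Initialise a CLAM-style model
#'
#' @param config A [clam_config()].
#' @param seed Integer seed for the parameter initialisation.
#' @return A `mil_model` of kind `"clam_sb"`.
#' @export
clam_init <- function(config = clam_config(), seed = 1L) {
  set.seed(seed)
  d <- config$input_dim; e <- config$encoder_hidden
  a <- config$attn_hidden; cc <- config$cls_hidden; k <- config$n_classes
  params <- list(
    W1 = .init_w(d, e), b1 = .init_b(e),
    Wa = .init_w(e, a), ba = .init_b(a),
    Wb = .init_w(e, a), bb = .init_b(a),
    wout = .init_w(a, 1L), cout = 0,
    W2 = .init_w(e, cc), b2 = .init_b(cc),
    W3 = .init_w(cc, k), b3 = .init_b(k),
    winst = .init_w(e, 1L), binst = 0
  )
  structure(list(kind = "clam_sb", params = params, config = config),
            class = "mil_model")
}

# Full forward pass; returns cache for the backward pass.
.clam_fwd <- function(params, config, x, train = FALSE) {
  dr <- config$dropout
  z1 <- .affine(x, params$W1, params$b1)
  h0 <- gelu(z1)
  m1 <- .dropout_mask(dim(h0), dr, train)
  h <- h0 * m1
  za <- .affine(h, params$Wa, params$ba); u <- tanh(za)
  zb <- .affine(h, params$Wb, params$bb); g <- .sigmoid(zb)
  p <- u * g
  mp <- .dropout_mask(dim(p), dr, train)
  pd <- p * mp
  s <- as.numeric(pd %*% params$wout) + params$cout
  attn <- .softmax(s)
  m <- as.numeric(crossprod(h, attn))
  z2 <- as.numeric(m %*% params$W2) + params$b2
  c0 <- gelu(z2)
  m2 <- .dropout_mask(length(c0), dr, train)
  cvec <- c0 * m2
  logits <- as.numeric(cvec %*% params$W3) + params$b3
  probs <- .softmax(logits)
  qz <- as.numeric(h %*% params$winst) + params$binst
  list(x = x, z1 = z1, m1 = m1, h = h, za = za, u = u, zb = zb, g = g,
       mp = mp, pd = pd, s = s, attn = attn, m = m, z2 = z2, m2 = m2,
       cvec = cvec, logits = logits, probs = probs, qz = qz,
       q = .sigmoid(qz))
}

#' Forward pass of the CLAM-style model
#'
#' Pipeline: per-instance encoder (GELU, dropout), gated attention
#' scores, softmax over instances, attention-weighted pooling, two-layer
#' GELU classifier. Eval mode disables dropout and is deterministic.
#'
#' @param model A `mil_model` from [clam_init()].
#' @param bag A [feature_bag()] or an N x D feature matrix.
#' @param train Enable dropout.
#' @return List with `logits`, `probs`, `attention` (list of simplex
#'   `weights` and `raw_scores`), and `instance_embeddings`.
#' @export
clam_forward <- function(model, bag, train = FALSE) {
  x <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  if (ncol(x) != model$config$input_dim) {
    stop("bag dimension ", ncol(x), " does not match config input_dim ",
         model$config$input_dim, call. = FALSE)
  }
  f <- .clam_fwd(model$params, model$config, x, train = train)
  list(logits = f$logits, probs = f$probs,
       attention = list(weights = f$attn, raw_scores = f$s),
       instance_embeddings = f$h)
}

# Top-k / bottom-k pseudo-label selection for the clustering loss.
.clam_inst_select <- function(attn, k_sample) {
  n <- length(attn)
  k_eff <- min(k_sample, n)
  ord <- order(attn, decreasing = TRUE)
  list(idx = c(ord[seq_len(k_eff)], rev(ord)[seq_len(k_eff)]),
       labels = rep(c(1, 0), each = k_eff))
}

#' Instance-clustering loss
#'
#' Mean binary cross-entropy of the instance classifier on pseudo-labels:
#' the `k_sample` most-attended instances are labelled positive and the
#' `k_sample` least-attended negative, constraining the attention to
#' separate diagnostic from background patches.
#'
#' @param attention_weights Length-N attention simplex.
#' @param instance_probs Length-N instance-classifier probabilities.
#' @param k_sample Instances drawn from each extreme (clamped to N).
#' @return Scalar loss.
#' @export
instance_cluster_loss <- function(attention_weights, instance_probs,
                                  k_sample = 8L) {
  sel <- .clam_inst_select(attention_weights, k_sample)
  q <- .clamp_probs(instance_probs[sel$idx])
  -mean(sel$labels * log(q) + (1 - sel$labels) * log(1 - q))
}

#' Composite CLAM loss
#'
#' `bag_weight * bag_loss + (1 - bag_weight) * instance_loss`.
#'
#' @param bag_loss,inst_loss Finite scalars.
#' @param bag_weight Weight in `[0, 1]`.
#' @return Scalar.
#' @export
clam_total_loss <- function(bag_loss, inst_loss, bag_weight = 0.5) {
  bag_weight * bag_loss + (1 - bag_weight) * inst_loss
}

# Loss + gradients for one bag. loss_spec: list(alpha, gamma, epsilon).
.clam_loss_grad <- function(model, x, tier, loss_spec, train = TRUE,
                            want_grads = TRUE) {
  p <- model$params; cfg <- model$config
  f <- .clam_fwd(p, cfg, x, train = train)
  k <- cfg$n_classes
  y_soft <- smooth_labels(tier, epsilon = loss_spec$epsilon, k = k)
  bag_loss <- focal_loss(f$probs, y_soft, alpha = loss_spec$alpha,
                         gamma = loss_spec$gamma)
  sel <- .clam_inst_select(f$attn, cfg$k_sample)
  inst_loss <- instance_cluster_loss(f$attn, f$q, cfg$k_sample)
  total <- clam_total_loss(bag_loss, inst_loss, cfg$bag_weight)
  if (!want_grads) return(list(loss = total, bag_loss = bag_loss,
                               inst_loss = inst_loss, probs = f$probs))
  bw <- cfg$bag_weight
  dlogits <- bw * .focal_grad_logits(f$probs, y_soft, loss_spec$alpha,
                                     loss_spec$gamma)
  dW3 <- outer(f$cvec, dlogits); db3 <- dlogits
  dcvec <- as.numeric(p$W3 %*% dlogits)
  dz2 <- dcvec * f$m2 * .gelu_grad(f$z2)
  dW2 <- outer(f$m, dz2); db2 <- dz2
  dm <- as.numeric(p$W2 %*% dz2)
  # pooling: m = t(H) %*% a
  dh <- outer(f$attn, dm)
  da <- as.numeric(f$h %*% dm)
  ds <- f$attn * (da - sum(da * f$attn))
  dwout <- crossprod(f$pd, ds); dcout <- sum(ds)
  dpd <- outer(ds, as.numeric(p$wout))
  dp_ <- dpd * f$mp
  du <- dp_ * f$g; dg <- dp_ * f$u
  dza <- du * (1 - f$u^2); dzb <- dg * f$g * (1 - f$g)
  dWa <- crossprod(f$h, dza); dba <- colSums(dza)
  dWb <- crossprod(f$h, dzb); dbb <- colSums(dzb)
  dh <- dh + dza %*% t(p$Wa) + dzb %*% t(p$Wb)
  # instance branch: L_inst = (1-bw) * mean BCE over 2*k_eff slots
  n_sel <- length(sel$idx)
  q_cl <- .clamp_probs(f$q)
  dqz <- rep(0, length(f$qz))
  contrib <- (1 - bw) * (q_cl[sel$idx] - sel$labels) / n_sel
  for (j in seq_along(sel$idx)) {
    dqz[sel$idx[j]] <- dqz[sel$idx[j]] + contrib[j]
  }
  dwinst <- crossprod(f$h, dqz); dbinst <- sum(dqz)
  dh <- dh + outer(dqz, as.numeric(p$winst))
  dz1 <- dh * f$m1 * .gelu_grad(f$z1)
  dW1 <- crossprod(f$x, dz1); db1 <- colSums(dz1)
  grads <- list(W1 = dW1, b1 = db1, Wa = dWa, ba = dba, Wb = dWb, bb = dbb,
                wout = dwout, cout = dcout, W2 = dW2, b2 = db2,
                W3 = dW3, b3 = db3, winst = dwinst, binst = dbinst)
  list(loss = total, bag_loss = bag_loss, inst_loss = inst_loss,
       probs = f$probs, grads = grads)
}
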