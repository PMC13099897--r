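tiny_abmil <- function(seed = 3L, merge = "mean") {
  abmil_init(abmil_config(input_dim = 5L, n_heads = 2L, attn_space = 4L,
                          head_dim = 6L, bottleneck = 5L, merge = merge),
             seed = seed)
}

test_that("gated head scores follow the tanh-gate-linear pipeline", {
  hp <- list(A = matrix(0, 5, 4), a = rep(0, 4), B = matrix(0, 5, 4),
             b = rep(0, 4), C = matrix(1, 4, 3), c = rep(0, 3))
  # zero weights and biases: tanh branch is 0 so all class scores are 0
  x <- matrix(rnorm(10 * 5), 10, 5)
  expect_true(all(gated_head_scores(x, hp) == 0))
  # duplicated instance rows give duplicated score rows
  m <- tiny_abmil()
  pre <- "h1_"
  hp2 <- list(P = m$params[["h1_P"]], A = m$params[["h1_A"]],
              a = m$params[["h1_a"]], B = m$params[["h1_B"]],
              b = m$params[["h1_b"]], C = m$params[["h1_C"]],
              c = m$params[["h1_c"]])
  xd <- rbind(x[1, ], x[1, ])
  sc <- gated_head_scores(xd, hp2)
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-12)
})

test_that("class attention columns are simplexes for all bag sizes", {
  m <- tiny_abmil()
  for (n in c(1L, 2L, 100L)) {
    set.seed(n)
    out <- abmil_forward(m, matrix(rnorm(n * 5), n, 5))
    expect_equal(colSums(out$attention), rep(1, 3), tolerance = 1e-6)
    expect_true(all(out$attention >= 0))
    if (n == 1L) expect_equal(as.numeric(out$attention), rep(1, 3))
  }
  # all-equal scores give uniform columns; single head merge is identity
  s <- matrix(2, 6, 3)
  expect_equal(class_attention(list(s)), matrix(1 / 6, 6, 3))
  expect_equal(class_attention(list(s, s + 1)),
               class_attention(list(s)))  # softmax shift invariance
  expect_error(class_attention(list()), "no attention heads")
})

test_that("three-branch aggregation matches the loop-summation oracle", {
  set.seed(5)
  x <- matrix(rnorm(7 * 5), 7, 5)
  attn <- wsimil:::.softmax_cols(matrix(rnorm(7 * 3), 7, 3))
  v <- three_branch_aggregate(x, attn)
  oracle <- matrix(0, 3, 5)
  for (c in 1:3) for (i in 1:7) oracle[c, ] <- oracle[c, ] + attn[i, c] * x[i, ]
  expect_equal(v, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # uniform attention returns the instance mean in every branch
  vu <- three_branch_aggregate(x, matrix(1 / 7, 7, 3))
  for (c in 1:3) expect_equal(as.numeric(vu[c, ]), colMeans(x),
                              tolerance = 1e-12)
  # one-hot attention selects that instance
  oh <- matrix(0, 7, 3); oh[4, ] <- 1
  expect_equal(as.numeric(three_branch_aggregate(x, oh)[2, ]), x[4, ],
               tolerance = 1e-12)
})

test_that("abmil end-to-end is permutation invariant and deterministic", {
  m <- tiny_abmil()
  set.seed(9)
  x <- matrix(rnorm(11 * 5), 11, 5)
  a <- abmil_forward(m, x)
  expect_identical(a$logits, abmil_forward(m, x)$logits)
  perm <- sample(11)
  expect_equal(abmil_forward(m, x[perm, ])$logits, a$logits,
               tolerance = 1e-6)
  expect_true(a$gate_mean > 0 && a$gate_mean < 1)
})

test_that("abmil gradients match finite differences (both merges)", {
  set.seed(7)
  x <- matrix(rnorm(4 * 5), 4, 5)
  spec <- list(alpha = c(1, 3, 1), gamma = 0, epsilon = 0)
  for (merge in c("mean", "concat")) {
    m <- tiny_abmil(merge = merge)
    out <- wsimil:::.abmil_loss_grad(m, x, 2L, spec, train = FALSE)
    ng <- num_grad(function(pp) {
      m2 <- m; m2$params <- pp
      wsimil:::.abmil_loss_grad(m2, x, 2L, spec,
                                want_grads = FALSE)$loss
    }, m$params)
    expect_lt(max_rel_err(out$grads, ng), 1e-4)
  }
})

test_that("identical branches differ in logits only via the readout", {
  m <- tiny_abmil()
  br <- matrix(rep(rnorm(5), each = 3), 3, 5)
  lg <- abmil_classify(br, m$params)
  # with identical branch rows, bottleneck outputs agree; any logit
  # difference comes from the per-class readout weights
  bt <- gelu(wsimil:::.affine(br, m$params$Wbot, m$params$bbot))
  expect_equal(bt[1, ], bt[2, ], tolerance = 1e-12)
  expect_equal(lg, as.numeric(bt %*% m$params$R)[c(1, 5, 9)] + m$params$d,
               tolerance = 1e-12)
})
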