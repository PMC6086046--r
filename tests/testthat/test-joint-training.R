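# Hand oracle: context text vector of the *second* vertex of an ordered pair,
# computed with explicit loops straight from the model parameters.
hand_context_vec <- function(m, cond, cand) {
  par <- m$par
  d <- m$dim; w <- m$config$conv_window
  emb <- function(ids) {
    E <- matrix(0, d, max(length(ids), w))  # zero-padded to window length
    for (k in seq_along(ids)) E[, k] <- par$Wword[ids[k], ]
    E
  }
  conv <- function(E) {
    mcols <- ncol(E) - w + 1L
    U <- matrix(0, d, mcols)
    for (t in seq_len(mcols)) {
      U[, t] <- par$Wconv %*% as.vector(E[, t:(t + w - 1)]) + par$bconv
    }
    U
  }
  U <- conv(emb(m$token_ids[[cond]]))
  V <- conv(emb(m$token_ids[[cand]]))
  C <- matrix(0, ncol(U), ncol(V))
  for (i in seq_len(ncol(U))) for (j in seq_len(ncol(V))) {
    C[i, j] <- tanh(sum(U[, i] * (par$A %*% V[, j, drop = FALSE])))
  }
  h_v <- apply(C, 2, mean)
  a_v <- exp(h_v - max(h_v)); a_v <- a_v / sum(a_v)
  as.vector(V %*% a_v)
}

hand_first_side <- function(m, cond, cand) {
  # mirror of hand_context_vec for the row (first) side
  par <- m$par
  full <- ontropy:::text_pair_forward(m$token_ids[[cond]], m$token_ids[[cand]],
                                      par$Wword, par$Wconv, par$bconv, par$A,
                                      m$config$conv_window)
  full$u_t
}

test_that("the exact joint objective matches a hand-evaluated softmax oracle", {
  g <- make_graph(rbind(c("B", "A"), c("C", "B")),
                  texts = c("host immune response", "viral replication process",
                            "dengue virion assembly"))
  m <- tiny_model(g, dim = 3, seed = 9)
  cfg <- m$config
  S <- m$par$S
  ui <- which(m$ids == "A"); vi <- which(m$ids == "B")
  us <- S[ui, ]; vs <- S[vi, ]
  Kt <- t(sapply(seq_along(m$ids), function(k) hand_context_vec(m, ui, k)))
  u_t <- hand_first_side(m, ui, vi)
  v_t <- Kt[vi, ]
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  expected <- (sum(us * vs) - lse(as.vector(S %*% us))) +
    cfg$alpha * (sum(u_t * v_t) - lse(as.vector(Kt %*% u_t))) +
    cfg$beta  * (sum(us * v_t) - lse(as.vector(Kt %*% us))) +
    cfg$gamma * (sum(u_t * vs) - lse(as.vector(S %*% u_t)))
  expect_equal(edge_objective(m, c("A", "B"), exact = TRUE), expected,
               tolerance = 1e-10)
})

test_that("weight degeneracies and linearity hold for the joint objective", {
  g <- path_graph(4)
  m <- tiny_model(g, dim = 3, seed = 4)

  # alpha = beta = gamma = 0 reduces exactly to the structure loss
  m0 <- m; m0$config$alpha <- 0; m0$config$beta <- 0; m0$config$gamma <- 0
  expect_equal(edge_objective(m0, c("A", "B"), exact = TRUE),
               structure_loss(m0, c("A", "B")))

  # the objective is linear in alpha: doubling it doubles the L_tt part
  obj_at <- function(a) {
    mm <- m; mm$config$alpha <- a
    edge_objective(mm, c("A", "B"), exact = TRUE)
  }
  expect_equal(obj_at(2) - obj_at(0), 2 * (obj_at(1) - obj_at(0)),
               tolerance = 1e-10)

  expect_error(edge_objective(m, c("A", "B"), negatives = character(0),
                              exact = FALSE),
               class = "ontropy_config_error")
})

test_that("analytic SGD gradients match finite differences of the objective", {
  g <- make_graph(rbind(c("B", "A"), c("C", "B"), c("D", "B")),
                  texts = c("alpha beta", "gamma delta epsilon",
                            "zeta eta", "theta iota kappa"))
  m <- tiny_model(g, dim = 3, seed = 8)
  par <- m$par
  u <- 2L; v <- 1L; negs <- c(3L, 4L)
  f <- function() ontropy:::edge_objective_idx(m, u, v, negs)
  lr <- 1e-7
  snap <- list(S = par$S, W = par$Wword, Wc = par$Wconv, b = par$bconv, A = par$A)
  acc <- new.env()
  ontropy:::edge_sgd_step(m, u, v, negs, lr, acc)
  analytic <- list(S = (par$S - snap$S) / lr, W = (par$Wword - snap$W) / lr,
                   Wc = (par$Wconv - snap$Wc) / lr, b = (par$bconv - snap$b) / lr,
                   A = (par$A - snap$A) / lr)
  par$S <- snap$S; par$Wword <- snap$W; par$Wconv <- snap$Wc
  par$bconv <- snap$b; par$A <- snap$A

  num_grad <- function(get, set) {
    base <- get(); gn <- base; eps <- 1e-5
    for (i in seq_along(base)) {
      x <- base; x[i] <- base[i] + eps; set(x); fp <- f()
      x[i] <- base[i] - eps; set(x); fm <- f()
      gn[i] <- (fp - fm) / (2 * eps)
    }
    set(base)
    gn
  }
  expect_equal(as.vector(analytic$S),
               as.vector(num_grad(function() par$S, function(x) par$S <- x)),
               tolerance = 1e-6)
  expect_equal(as.vector(analytic$W),
               as.vector(num_grad(function() par$Wword, function(x) par$Wword <- x)),
               tolerance = 1e-6)
  expect_equal(as.vector(analytic$Wc),
               as.vector(num_grad(function() par$Wconv, function(x) par$Wconv <- x)),
               tolerance = 1e-6)
  expect_equal(as.vector(analytic$b),
               as.vector(num_grad(function() par$bconv, function(x) par$bconv <- x)),
               tolerance = 1e-6)
  expect_equal(as.vector(analytic$A),
               as.vector(num_grad(function() par$A, function(x) par$A <- x)),
               tolerance = 1e-6)
})

test_that("training is seed-deterministic, records history, and can be frozen", {
  g <- synth_ontology(synth_config(n_classes = 12, seed = 21))
  cfg <- joint_config(dim = 8, epochs = 3, seed = 5, walks_per_vertex = 2,
                      walk_length = 10)
  m1 <- train_embeddings(g, cfg)
  m2 <- train_embeddings(g, cfg)
  expect_identical(m1$par$S, m2$par$S)
  expect_identical(m1$par$Wword, m2$par$Wword)
  expect_identical(m1$par$A, m2$par$A)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_length(m1$loss_history, 3L)
  expect_true(all(is.finite(m1$loss_history)))

  frozen <- train_embeddings(g, joint_config(dim = 8, epochs = 3, seed = 5,
                                             learning_rate = 0,
                                             walks_per_vertex = 2,
                                             walk_length = 10))
  expect_equal(stats::sd(c(frozen$initial_objective, frozen$loss_history)), 0)
})

test_that("a single-edge graph trains to finite vectors", {
  g <- make_graph(rbind(c("A", "B")),
                  texts = c("first class text", "second class text"))
  m <- train_embeddings(g, joint_config(dim = 4, epochs = 2, seed = 1,
                                        negatives = 1))
  expect_true(all(is.finite(m$par$S)))
  expect_true(all(is.finite(vertex_embeddings(m, "full"))))
})

test_that("zero text weights leave the text parameters untouched", {
  g <- path_graph(4)
  m <- tiny_model(g, dim = 3, seed = 2)
  m$config$alpha <- 0; m$config$beta <- 0; m$config$gamma <- 0
  before <- list(W = m$par$Wword, Wc = m$par$Wconv, b = m$par$bconv, A = m$par$A,
                 S = m$par$S)
  acc <- new.env()
  ontropy:::edge_sgd_step(m, 1L, 2L, 3L, lr = 0.1, acc)
  expect_identical(m$par$Wword, before$W)
  expect_identical(m$par$A, before$A)
  expect_false(identical(m$par$S, before$S))
})

test_that("the joint objective ascends on a small synthetic ontology", {
  g <- synth_ontology(synth_config(n_classes = 25, seed = 31))
  gains <- vapply(1:3, function(s) {
    m <- train_embeddings(g, joint_config(epochs = 5, seed = s, dim = 16))
    tail(m$loss_history, 1) - m$initial_objective
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("final embeddings concatenate the structure and text halves", {
  g <- path_graph(3)
  m <- tiny_model(g, dim = 3, seed = 12)
  full <- vertex_embeddings(m, "full")
  expect_equal(ncol(full), 6L)
  expect_equal(unname(full[, 1:3]), unname(vertex_embeddings(m, "structure")))
  expect_equal(unname(full[, 4:6]), unname(vertex_embeddings(m, "text")))
  expect_equal(final_vertex_embedding(m, "B"), full["B", ])
  expect_error(final_vertex_embedding(m, "nope"), class = "ontropy_lookup_error")

  # aggregate text vector is the mean of per-neighbor context vectors
  bi <- which(m$ids == "B")
  hand <- (ontropy:::context_text_vector(m, which(m$ids == "A"), bi) +
             ontropy:::context_text_vector(m, which(m$ids == "C"), bi)) / 2
  expect_equal(unname(full["B", 4:6]), hand)
})

test_that("checkpoints round-trip through plain-text files", {
  g <- synth_ontology(synth_config(n_classes = 10, seed = 2))
  m <- train_embeddings(g, joint_config(dim = 6, epochs = 2, seed = 3,
                                        walks_per_vertex = 2, walk_length = 10))
  dir <- file.path(tempdir(), "ckpt-test")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m2$par$S, m$par$S)
  expect_equal(m2$par$A, m$par$A, tolerance = 1e-12)
  expect_equal(m2$loss_history, m$loss_history)
  expect_equal(eapb_entropy(g, m2)$s_prime, eapb_entropy(g, m)$s_prime,
               tolerance = 1e-10)
})
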