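test_that("hill climbing recovers a linear chain and rejects nothing spurious", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    a <- rnorm(500); b <- a + rnorm(500, 0, 0.3); c_ <- b + rnorm(500, 0, 0.3)
    g <- learn_structure(data.frame(a = a, b = b, c = c_))
    e <- generics::tidy(g)
    skel <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    hits <- hits + identical(skel, c("a b", "b c"))
  }
  expect_gte(hits / 30, 0.95)
})

test_that("independent variables yield an (almost always) empty graph", {
  # BIC admits a spurious edge when a sample partial correlation exceeds
  # sqrt(log(n)/n) ~ 0.11; over 6 pairs at n = 500 that leaves ~93% of
  # datasets empty, so assert a level the binomial noise cannot break
  empties <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    g <- learn_structure(matrix(rnorm(500 * 4), 500, 4))
    empties <- empties + (sum(g$adj) == 0)
  }
  expect_gte(empties / 100, 0.85)
})

test_that("score-equivalent duplicate columns give one edge, fixed by tie-break", {
  set.seed(2)
  x <- rnorm(200)
  d <- data.frame(v1 = x, v2 = x + rnorm(200, 0, 1e-4))
  g <- learn_structure(d)
  expect_equal(sum(g$adj), 1L)
  g2 <- learn_structure(d)
  expect_identical(g$adj, g2$adj)  # deterministic
})

test_that("compiled and reference search engines agree move for move", {
  for (s in 1:5) {
    set.seed(3000 + s)
    n <- 120; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    X[, 2] <- X[, 1] + rnorm(n, 0, 0.5)
    X[, 5] <- X[, 2] - X[, 3] + rnorm(n, 0, 0.5)
    colnames(X) <- paste0("v", 1:p)
    gr <- learn_structure(X, engine = "r")
    gc_ <- learn_structure(X, engine = "cpp")
    expect_identical(gr$adj, gc_$adj)
    expect_equal(gr$score, gc_$score, tolerance = 1e-8)
  }
})

test_that("constant columns and tiny samples are rejected", {
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(learn_structure(X), class = "scfamap_domain_error")
  expect_error(learn_structure(X), "b")
  expect_error(learn_structure(matrix(rnorm(8), 4, 2)),
               class = "scfamap_domain_error")
})

test_that("bootstrap consensus retains the true skeleton of the chain", {
  set.seed(11)
  a <- rnorm(500); b <- a + rnorm(500, 0, 0.3); c_ <- b + rnorm(500, 0, 0.3)
  net <- bootstrap_consensus(data.frame(a = a, b = b, c = c_),
                             n_boot = 50, seed = 1)
  expect_true(all(net$edge_freq$frequency >= 0 & net$edge_freq$frequency <= 1))
  ret <- net$retained
  skel <- sort(paste(pmin(ret$from, ret$to), pmax(ret$from, ret$to)))
  expect_identical(skel, c("a b", "b c"))
  expect_true(all(ret$frequency > 0.9))
  expect_false("a c" %in% skel)
})

test_that("single-bootstrap consensus equals the single learned graph", {
  set.seed(21)
  a <- rnorm(200); b <- a + rnorm(200, 0, 0.3)
  d <- data.frame(a = a, b = b)
  net <- bootstrap_consensus(d, n_boot = 1, seed = 9)
  expect_true(all(net$edge_freq$frequency %in% c(0, 1)))
  set.seed(9)  # reproduce the single resample the consensus drew
  idx <- sample.int(200, 200, replace = TRUE)
  g <- learn_structure(d[idx, ])
  expect_equal(nrow(net$retained), sum(g$adj))
  expect_error(bootstrap_consensus(d, n_boot = 0), class = "scfamap_config_error")
})

test_that("raising the retention threshold only shrinks the retained set", {
  set.seed(31)
  n <- 150
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.8); c_ <- rnorm(n); d_ <- c_ + b + rnorm(n)
  dat <- data.frame(a = a, b = b, c = c_, d = d_)
  nets <- lapply(c(0.3, 0.5, 0.8), function(r)
    bootstrap_consensus(dat, n_boot = 40, retention = r, seed = 2))
  key <- function(net) paste(pmin(net$retained$from, net$retained$to),
                             pmax(net$retained$from, net$retained$to))
  expect_true(all(key(nets[[2]]) %in% key(nets[[1]])))
  expect_true(all(key(nets[[3]]) %in% key(nets[[2]])))
})

test_that("pure-noise data retains no consensus edges in most seeds", {
  # a dataset whose luckiest sample correlation clears the BIC bar keeps
  # that edge across bootstraps, which happens in roughly 10% of datasets
  # at this size; assert the complementary majority with binomial margin
  clean <- 0L
  for (s in 1:20) {
    set.seed(4000 + s)
    net <- bootstrap_consensus(matrix(rnorm(500 * 4), 500, 4),
                               n_boot = 30, seed = s)
    clean <- clean + (nrow(net$retained) == 0)
  }
  expect_gte(clean / 20, 0.8)
})

test_that("SCFA neighborhood classification distinguishes direct, indirect, none", {
  net <- structure(list(
    nodes = c("t1", "t2", "t3", "acetate", "transit"),
    edge_freq = tibble::tibble(),
    retained = tibble::tibble(from = c("t1", "t2"),
                              to = c("t2", "acetate"),
                              frequency = c(0.9, 0.8),
                              direction = "forward", sign = 1),
    n_boot = 10, retention = 0.5, seed = 1), class = "consensus_network")
  nb <- scfa_neighborhood(net, "acetate")
  expect_equal(nb$status[nb$node == "t2"], "direct")
  expect_equal(nb$status[nb$node == "t1"], "indirect")
  expect_equal(nb$status[nb$node == "t3"], "none")
  expect_equal(nb$status[nb$node == "transit"], "none")
  expect_error(scfa_neighborhood(net, "nope"), class = "scfamap_key_error")

  net$retained <- net$retained[0, ]
  nb0 <- scfa_neighborhood(net, "acetate")
  expect_true(all(nb0$status == "none"))
})

test_that("cycle breaking drops the weakest edge of a directed cycle", {
  ret <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"),
                        frequency = c(0.9, 0.8, 0.6),
                        direction = "forward", sign = 1)
  fixed <- scfamap:::break_cycles(ret)
  expect_equal(nrow(fixed), 2)
  expect_false(any(fixed$from == "c" & fixed$to == "a"))
})

test_that("consensus edge frequencies are invariant to input row order", {
  set.seed(51)
  n <- 100
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.4)
  d <- data.frame(a = a, b = b, c = rnorm(n))
  n1 <- bootstrap_consensus(d, n_boot = 25, seed = 3)
  # the learner only sees the empirical distribution, so a strong edge keeps
  # its consensus frequency when rows are shuffled
  perm <- sample.int(n)
  n2 <- bootstrap_consensus(d[perm, ], n_boot = 25, seed = 3)
  freq_ab <- function(net) {
    e <- net$edge_freq
    f <- e$frequency[(e$from == "a" & e$to == "b") |
                       (e$from == "b" & e$to == "a")]
    if (length(f) == 0) 0 else f
  }
  expect_gt(freq_ab(n1), 0.9)
  expect_gt(freq_ab(n2), 0.9)
})
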