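# CI-test closure over a mixed_data object, as mixed_pc builds internally
test_closure <- function(md, method = "mm") {
  function(x, y, S)
    suppressWarnings(symmetric_test(x, y, S, md, method = method)$pvalue)
}

test_that("skeleton search removes all edges among independent variables", {
  set.seed(73)
  n <- 5000
  md <- mixed_data(data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n)),
                   list(spec_cont("a"), spec_cont("b"), spec_cont("c")))
  sk <- pc_skeleton(md, test_closure(md), alpha = 0.01)
  expect_identical(n_edges(sk$graph), 0L)
  expect_identical(sk$n_tests[1], 3L)     # p(p-1)/2 tests at level 0
})

test_that("skeleton search recovers a chain and records its separating set", {
  set.seed(79)
  n <- 5000
  x <- rnorm(n); z <- 0.8 * x + rnorm(n); y <- 0.8 * z + rnorm(n)
  md <- mixed_data(data.frame(x = x, z = z, y = y),
                   list(spec_cont("x"), spec_cont("z"), spec_cont("y")))
  sk <- pc_skeleton(md, test_closure(md), alpha = 0.01)
  e <- pdag_edges(sk$graph)
  expect_identical(nrow(e$directed), 0L)
  expect_setequal(paste(e$undirected[, 1], e$undirected[, 2]), c("x z", "y z"))
  expect_identical(get(paste(sort(c("x", "y")), collapse = "\r"),
                       envir = sk$sepsets), "z")
})

test_that("PC output is invariant under column permutation of the input", {
  dag <- sample_dag(7, 2, seed = 83)
  eqs <- sample_parameters(dag, seed = 84)
  md <- sample_data(dag, eqs, 800, seed = 85)
  fit1 <- suppressMessages(mixed_pc(md, alpha = 0.05, method = "mm"))
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  md2 <- mixed_data(md$data[, perm], md$specs[perm])
  fit2 <- suppressMessages(mixed_pc(md2, alpha = 0.05, method = "mm"))
  expect_true(fit1$graph == fit2$graph)
})

test_that("collider data orient both arrows into the collision node", {
  set.seed(89)
  n <- 5000
  x <- rnorm(n); y <- rnorm(n); z <- 0.9 * x - 0.8 * y + rnorm(n)
  md <- mixed_data(data.frame(x = x, y = y, z = z),
                   list(spec_cont("x"), spec_cont("y"), spec_cont("z")))
  fit <- mixed_pc(md, alpha = 0.01)
  e <- pdag_edges(fit$graph)
  expect_setequal(paste(e$directed[, 1], e$directed[, 2]), c("x z", "y z"))
  # common cause: no orientation possible (the fork equals the chain class)
  x2 <- 0.9 * z + rnorm(n); y2 <- -0.7 * z + rnorm(n)
  md2 <- mixed_data(data.frame(x = x2, y = y2, z = z),
                    list(spec_cont("x"), spec_cont("y"), spec_cont("z")))
  fit2 <- mixed_pc(md2, alpha = 0.01)
  e2 <- pdag_edges(fit2$graph)
  expect_identical(nrow(e2$directed), 0L)
  expect_identical(nrow(e2$undirected), 2L)
})

test_that("shielded triples are never oriented by the collider rule", {
  g <- pdag(c("a", "b", "c"),
            undirected = rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  sep <- new.env()
  out <- orient_v_structures(g, sep)   # triangle: nothing unshielded
  expect_true(out == g)
  # missing sepset for a genuinely unshielded pair is an error
  g2 <- pdag(c("a", "b", "c"), undirected = rbind(c("a", "b"), c("b", "c")))
  expect_error(orient_v_structures(g2, sep), "no separating set")
})

test_that("conflicting collider claims leave the edge undirected", {
  # a - b - c - d path with (wrong) sepsets forcing b -> c and c -> b claims
  g <- pdag(c("a", "b", "c", "d"),
            undirected = rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  sep <- new.env()
  assign(paste(sort(c("a", "c")), collapse = "\r"), character(0), sep)
  assign(paste(sort(c("b", "d")), collapse = "\r"), character(0), sep)
  assign(paste(sort(c("a", "d")), collapse = "\r"), "b", sep)
  out <- suppressMessages(orient_v_structures(g, sep))
  # b - c claimed in both directions: left undirected; outer arrows stand
  expect_identical(unname(out$amat["b", "c"] + out$amat["c", "b"]), 2L)
  expect_identical(unname(out$amat["b", "a"]), 0L)  # a -> b
  expect_identical(unname(out$amat["c", "d"]), 0L)  # d -> c
})

test_that("Meek rules orient chains, cascades and reach a fixpoint", {
  # R1: x -> z, z - y, x and y non-adjacent  =>  z -> y
  g <- pdag(c("x", "y", "z"), directed = rbind(c("x", "z")),
            undirected = rbind(c("z", "y")))
  out <- apply_meek_rules(g)
  expect_identical(unname(out$amat["z", "y"]), 1L)
  expect_identical(unname(out$amat["y", "z"]), 0L)
  # R2: a -> c -> b with a - b  =>  a -> b
  g2 <- pdag(c("a", "b", "c"), directed = rbind(c("a", "c"), c("c", "b")),
             undirected = rbind(c("a", "b")))
  out2 <- apply_meek_rules(g2)
  expect_identical(unname(out2$amat["b", "a"]), 0L)
  # fully undirected graph with no v-structures: unchanged
  g3 <- pdag(c("a", "b", "c"), undirected = rbind(c("a", "b"), c("b", "c")))
  expect_true(apply_meek_rules(g3) == g3)
  # idempotence on a mixed graph
  out4 <- apply_meek_rules(out2)
  expect_true(apply_meek_rules(out4) == out4)
})

test_that("alpha near 1 keeps the complete skeleton", {
  md <- tiny_mixed(80, seed = 97)
  sk <- pc_skeleton(md, test_closure(md), alpha = 1 - 1e-12, max_k = 0)
  expect_identical(n_edges(sk$graph), 3L)
})

test_that("mm and fast learn the same skeleton on large-sample data", {
  dag <- sample_dag(6, 2, seed = 301, type_probs = c(0.5, 0.25, 0.25))
  eqs <- sample_parameters(dag, seed = 302)
  md <- sample_data(dag, eqs, 8000, seed = 303)
  skel_of <- function(m) {
    a <- suppressMessages(mixed_pc(md, alpha = 0.01, method = m))$graph$amat
    (a + t(a)) > 0
  }
  expect_identical(skel_of("mm"), skel_of("fast"))
})

test_that("PC on a sparse mixed DAG recovers the true CPDAG at large n", {
  dag <- sample_dag(6, 1.5, seed = 211)
  eqs <- sample_parameters(dag, seed = 212)
  md <- sample_data(dag, eqs, 10000, seed = 213)
  fit <- suppressMessages(mixed_pc(md, alpha = 0.01, method = "mm"))
  expect_true(fit$graph == dag_to_cpdag(dag))
})

test_that("skeleton soundness at scale: mean F1 over random 10-node DAGs", {
  set.seed(401)
  f1 <- replicate(20, {
    dag <- sample_dag(10, 2)
    eqs <- sample_parameters(dag)
    md <- sample_data(dag, eqs, 5000)
    gm <- graph_metrics(suppressMessages(mixed_pc(md, alpha = 0.01))$graph,
                        dag_to_cpdag(dag))
    2 / (1 / max(gm$skeleton_precision, 1e-9) +
           1 / max(gm$skeleton_recall, 1e-9))
  })
  expect_gte(mean(f1), 0.9)
})

test_that("PC with a d-separation oracle recovers the true CPDAG exactly", {
  # with a perfect conditional-independence oracle the whole chain --
  # PC-stable skeleton, sepset recording, collider orientation, Meek
  # completion -- must reproduce dag_to_cpdag(truth) on every input
  dsep <- function(dag, x, y, S) {
    pa <- dag$parents
    anc <- unique(c(x, y, S))
    repeat {
      new <- setdiff(unique(unlist(pa[anc])), anc)
      if (!length(new)) break
      anc <- c(anc, new)
    }
    adj <- matrix(FALSE, length(anc), length(anc), dimnames = list(anc, anc))
    for (ch in anc) {
      prs <- intersect(pa[[ch]], anc)
      for (q in prs) { adj[q, ch] <- TRUE; adj[ch, q] <- TRUE }
      if (length(prs) > 1) for (cb in combn(prs, 2, simplify = FALSE)) {
        adj[cb[1], cb[2]] <- TRUE; adj[cb[2], cb[1]] <- TRUE }
    }
    keep <- setdiff(anc, S)
    adjk <- adj[keep, keep, drop = FALSE]
    reach <- x
    repeat {
      nb <- unique(unlist(lapply(reach, function(v) keep[adjk[v, ]])))
      new <- setdiff(nb, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    !(y %in% reach)
  }
  set.seed(501)
  for (r in 1:15) {
    dag <- sample_dag(10, 3)
    fake_md <- structure(list(specs = dag$specs, data = data.frame(x = 1)),
                         class = "mixed_data")
    oracle <- function(a, b, S) if (dsep(dag, a, b, S)) 1 else 0
    sk <- pc_skeleton(fake_md, oracle, alpha = 0.5)
    g <- suppressMessages(
      apply_meek_rules(orient_v_structures(sk$graph, sk$sepsets)))
    expect_true(g == dag_to_cpdag(dag))
  }
})
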