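test_that("median discretization applies the >= rule", {
  m <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                1, 2, 2, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  d <- discretize_by_median(m)
  expect_equal(as.character(d$a), c("low", "low", "high", "high"))
  expect_equal(as.character(d$b), rep("high", 4))
  expect_equal(as.character(d$c), c("low", "high", "high", "high"))
  expect_equal(rownames(d), paste0("s", 1:4))
})

test_that("pathology nodes encode diagnosis and metastasis correctly", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  d <- discretize_by_median(m)
  samples <- data.frame(specimen_id = paste0("s", 1:4),
                        diagnosis = c("CP", "PDAC", "PDAC", "healthy"),
                        metastasis = c(NA, "M1", "M0", NA))
  out <- add_pathology_nodes(d, samples)
  expect_equal(as.character(out$cancer), c("false", "true", "true", "false"))
  expect_equal(as.character(out$pancreatitis),
               c("true", "false", "false", "false"))
  expect_equal(as.character(out$metastasis),
               c("false", "true", "false", "false"))
  samples$diagnosis[4] <- "IPMN"
  expect_error(add_pathology_nodes(d, samples), "unknown diagnosis")
})

test_that("the BIC family score matches hand arithmetic", {
  d <- data.frame(x = factor(c("high", "high", "high", "low"),
                             levels = c("low", "high")))
  expect_equal(bic_family_score("x", character(0), d),
               3 * log(3 / 4) + 1 * log(1 / 4) - 0.5 * log(4),
               tolerance = 1e-12)
  expect_error(bic_family_score("x", "x", d), "own parent")
})

test_that("an irrelevant parent lowers the score; a deterministic parent raises it", {
  lowered <- 0L
  for (r in 1:50) {
    d <- sim_discrete_bn(list(a = character(0), b = character(0)),
                         list(a = 0.5, b = 0.4), n = 200, seed = 900L + r)
    s0 <- bic_family_score("b", character(0), d)
    s1 <- bic_family_score("b", "a", d)
    if (s1 < s0) lowered <- lowered + 1L
  }
  expect_gte(lowered / 50, 0.95)

  d <- sim_discrete_bn(list(a = character(0), b = "a"),
                       list(a = 0.5, b = c(0, 1)), n = 100, seed = 1L)
  expect_gt(bic_family_score("b", "a", d),
            bic_family_score("b", character(0), d))
})

test_that("tabu search is deterministic and finds the empty graph on independent data", {
  d <- sim_discrete_bn(list(w = character(0), x = character(0),
                            y = character(0), z = character(0)),
                       list(w = 0.5, x = 0.3, y = 0.7, z = 0.4),
                       n = 500, seed = 2L)
  g1 <- tabu_search(d)
  g2 <- tabu_search(d)
  expect_identical(dag_edges(g1), dag_edges(g2))
  expect_identical(g1$score, g2$score)
  e <- exhaustive_search(d)
  expect_equal(g1$score, e$score, tolerance = 1e-9)
  expect_equal(nrow(dag_edges(g1)), 0L)
  expect_error(tabu_search(d, max_iter = 0), "max_iter")
})

test_that("a strong chain is recovered up to Markov equivalence", {
  d <- sim_discrete_bn(list(A = character(0), B = "A", C = "B"),
                       list(A = 0.5, B = c(0.9, 0.1), C = c(0.85, 0.15)),
                       n = 500, seed = 3L)
  g <- tabu_search(d)
  e <- exhaustive_search(d)
  expect_equal(g$score, e$score, tolerance = 1e-9)
  edges <- dag_edges(g)
  skel <- unique(t(apply(edges, 1, sort)))
  expect_equal(nrow(skel), 2L)
  expect_true(all(apply(skel, 1, paste, collapse = "-") %in%
                    c("A-B", "B-C")))   # no A-C edge
})

test_that("exhaustive search handles 1-node, independent and correlated pairs", {
  d1 <- data.frame(a = factor(c("low", "high", "low", "high")))
  e1 <- exhaustive_search(d1)
  expect_equal(nrow(dag_edges(e1)), 0L)

  d2 <- sim_discrete_bn(list(a = character(0), b = character(0)),
                        list(a = 0.5, b = 0.5), n = 1000, seed = 4L)
  expect_equal(nrow(dag_edges(exhaustive_search(d2))), 0L)

  d3 <- sim_discrete_bn(list(a = character(0), b = "a"),
                        list(a = 0.5, b = c(0.02, 0.98)), n = 1000, seed = 5L)
  e3 <- exhaustive_search(d3)
  expect_equal(nrow(dag_edges(e3)), 1L)
  # both orientations score identically; tie-break picks the least edge set
  d3swap <- d3[, c("b", "a")]
  e3b <- exhaustive_search(d3swap)
  expect_equal(e3$score, e3b$score, tolerance = 1e-9)
  expect_error(exhaustive_search(cbind(d2, d3, d1[rep(1, 1000), ,
                                                  drop = FALSE])),
               "at most 4")
})

test_that("every accepted tabu state is acyclic and scores decompose", {
  d <- sim_discrete_bn(list(A = character(0), B = "A", C = "B", D = "C"),
                       list(A = 0.5, B = c(0.8, 0.2), C = c(0.75, 0.25),
                            D = c(0.7, 0.3)), n = 300, seed = 6L)
  g <- tabu_search(d)
  # topological order must exist
  parents <- g$parents
  rem <- g$nodes
  repeat {
    roots <- rem[vapply(parents[rem], function(p) !any(p %in% rem),
                        logical(1))]
    expect_gt(length(roots), 0)
    rem <- setdiff(rem, roots)
    if (!length(rem)) break
  }
  expect_equal(g$score, sum(vapply(g$nodes, function(j)
    bic_family_score(j, g$parents[[j]], d), numeric(1))),
    tolerance = 1e-9)
})

test_that("neighborhood returns parents, children and the induced subnetwork", {
  dag <- structure(list(nodes = c("A", "B", "C"),
                        parents = list(A = character(0), B = "A", C = "B"),
                        score = 0), class = "ev_dag")
  nb <- neighborhood(dag, "B")
  expect_equal(nb$causes, "A")
  expect_equal(nb$consequences, "C")
  expect_equal(nrow(nb$subnetwork), 2L)
  iso <- structure(list(nodes = c("A", "B"),
                        parents = list(A = character(0), B = character(0)),
                        score = 0), class = "ev_dag")
  nbi <- neighborhood(iso, "A")
  expect_equal(length(nbi$causes) + length(nbi$consequences), 0L)
  expect_error(neighborhood(dag, "Z"), "unknown node")
})
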