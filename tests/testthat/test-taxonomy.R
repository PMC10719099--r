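test_that("type centroids equal brute-force group means", {
  set.seed(8)
  x <- matrix(rpois(100, 5), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("n", 1:10)))
  types <- rep(c("u", "v"), each = 5)
  cent <- computeTypeCentroids(x, types)
  oracle <- t(sapply(c("u", "v"), function(tp)
    apply(x[, types == tp], 1, mean)))
  expect_equal(cent, oracle, ignore_attr = TRUE)
  expect_equal(unname(computeTypeCentroids(
    matrix(c(0, 2), 1, 2, dimnames = list("g", c("a", "b"))),
    c("t", "t"))[1, 1]), 1)
  expect_error(computeTypeCentroids(x, factor(types, levels = c("u", "v", "w"))),
               "empty type")
})

test_that("taxonomy tree reproduces average-linkage structure", {
  # two identical centroids among three merge first at height 0
  cent <- rbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = c(5, 1, 0, 2))
  tree <- buildTaxonomyTree(cent, metric = "euclidean")
  expect_equal(tree$height[1], 0)
  expect_setequal(tree$labels[-tree$merge[1, ]], c("a", "b"))

  # collinear centroids: nearest pair merges first
  cl <- rbind(p = c(0, 0), q = c(1, 0), r = c(11, 0))
  tr <- buildTaxonomyTree(cl, metric = "euclidean")
  expect_setequal(tr$labels[-tr$merge[1, ]], c("p", "q"))

  # merge heights agree with a brute-force O(n^3) average-linkage oracle
  set.seed(9)
  cents <- matrix(rnorm(6 * 8), 6, 8,
                  dimnames = list(paste0("t", 1:6), NULL))
  tree6 <- buildTaxonomyTree(cents, metric = "euclidean")
  expect_equal(tree6$height, bruteAverageLinkage(dist(cents)),
               tolerance = 1e-12)
  expect_error(buildTaxonomyTree(rbind(x = 1:3, x = 2:4)), "duplicate")
})

test_that("tree order gives sequential ids and is permutation-stable", {
  set.seed(10)
  cents <- matrix(rnorm(5 * 20), 5, 20,
                  dimnames = list(paste0("t", 1:5), NULL))
  tree <- buildTaxonomyTree(cents)
  ids <- typeIdsFromTree(tree)
  expect_setequal(ids, 1:5)
  # permuting the type rows yields an isomorphic dendrogram
  perm <- c(3, 1, 5, 2, 4)
  tree2 <- buildTaxonomyTree(cents[perm, ])
  expect_equal(sort(tree$height), sort(tree2$height), tolerance = 1e-12)
  co <- stats::cophenetic(tree)
  co2 <- stats::cophenetic(tree2)
  m <- as.matrix(co)[paste0("t", 1:5), paste0("t", 1:5)]
  m2 <- as.matrix(co2)[paste0("t", 1:5), paste0("t", 1:5)]
  expect_equal(m, m2, tolerance = 1e-12)
  nwk <- exportNewick(tree)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("hierarchy has three divisions at the first split surface", {
  pipe <- smallPipeline()
  sim <- smallAtlas()
  cent <- computeTypeCentroids(pipe$norm, sim$truth$type)
  tree <- buildTaxonomyTree(cent)
  h <- buildHierarchy(tree, n_divisions = 3, n_subclasses = 4)
  expect_equal(length(unique(h$division)), 3)
  expect_equal(sort(h$type_id), seq_len(nrow(h)))
  # subclasses nest inside divisions
  nest <- table(h$subclass, h$division)
  expect_true(all(rowSums(nest > 0) == 1))
  ov <- buildHierarchy(tree, division_overrides =
                         stats::setNames("modulatory", h$type[1]))
  expect_equal(ov$division[ov$type == h$type[1]], "modulatory")
})

test_that("module scores subtract expression-matched controls", {
  set.seed(11)
  ng <- 250
  x <- matrix(rpois(ng * 60, 5), ng, 60,
              dimnames = list(paste0("g", seq_len(ng)), paste0("n", 1:60)))
  # whole-gene-universe module with exhaustive controls scores exactly 0
  sc <- scoreGeneModule(x, rownames(x), n_control_bins = 25,
                        n_control_per_gene = ng)
  expect_equal(unname(sc), rep(0, 60), tolerance = 1e-12)
  # a nucleus with uniform expression scores 0 for any module
  u <- matrix(3, ng, 2, dimnames = list(rownames(x), c("u1", "u2")))
  sc_u <- scoreGeneModule(u, paste0("g", 1:20), n_control_per_gene = 50)
  expect_equal(unname(sc_u), c(0, 0), tolerance = 1e-12)
  expect_error(scoreGeneModule(x, "nope"), "not present")
  # determinism under a fixed seed
  s1 <- scoreGeneModule(x, paste0("g", 1:10), seed = 2)
  s2 <- scoreGeneModule(x, paste0("g", 1:10), seed = 2)
  expect_identical(s1, s2)
})

test_that("a planted up-regulated module separates its nuclei", {
  set.seed(12)
  ng <- 400; n <- 200
  mu <- c(rep(8, 40), rexp(ng - 40, 1 / 5))
  x <- matrix(rpois(ng * n, mu), ng, n,
              dimnames = list(paste0("g", seq_len(ng)), paste0("c", seq_len(n))))
  on <- seq_len(n / 2)
  mod <- paste0("g", 1:40)
  x[mod, on] <- matrix(rpois(40 * length(on), mu[1:40] * 2), 40)
  norm <- log1p(t(t(x) / colSums(x)) * 1e4)
  sc <- scoreGeneModule(norm, mod, seed = 5)
  acc <- mean((sc > 0) == (seq_len(n) %in% on))
  expect_gte(acc, 0.95)
})

test_that("LIM groups are assigned by winning median module score", {
  lim_sets <- c("Lmx1b", "Lhx2/9", "Lhx3/4", "Lhx1/5")
  mkscores <- function(n, means) {
    m <- sapply(means, function(mm) rnorm(n, mm, 0.05))
    colnames(m) <- lim_sets
    m
  }
  set.seed(13)
  # forced single-group case
  s1 <- mkscores(40, c(-0.2, 0.8, -0.1, -0.3))
  a1 <- assignLIMGroup(s1, rep("T1", 40))
  expect_equal(a1$group, "Lhx2/9")
  # all-negative -> unassigned with warning
  s0 <- mkscores(40, c(-1, -1, -1, -1))
  expect_warning(a0 <- assignLIMGroup(s0, rep("T0", 40)), "unassigned")
  expect_true(is.na(a0$group))
  # combined group when Lhx1/5 and Lhx3/4 medians are close and positive
  sc <- mkscores(40, c(-0.5, -0.2, 0.62, 0.6))
  ac <- assignLIMGroup(sc, rep("TC", 40))
  expect_equal(ac$group, "Lhx1/5+Lhx3/4")
  expect_true(ac$combined)
  # five-group synthetic: 100% type-level recovery
  truth <- c(T1 = "Lmx1b", T2 = "Lhx2/9", T3 = "Lhx3/4", T4 = "Lhx1/5",
             T5 = "Lhx1/5+Lhx3/4")
  means <- list(c(1, -.2, -.2, -.2), c(-.2, 1, -.2, -.2),
                c(-.2, -.2, 1, -.2), c(-.2, -.2, -.2, 1),
                c(-.2, -.2, .9, .95))
  scores <- do.call(rbind, lapply(means, mkscores, n = 50))
  types <- rep(names(truth), each = 50)
  got <- assignLIMGroup(scores, types)
  expect_identical(stats::setNames(got$group, got$type), truth)
})
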