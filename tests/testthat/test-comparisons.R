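test_that("Venn regions partition the union", {
  vp <- venn_partition(list(A = "x", B = "x"))
  expect_equal(venn_region(vp, c("A", "B")), "x")
  expect_length(venn_region(vp, "A"), 0L)
  expect_error(venn_partition(list(A = "x")), "2 to 4")
  expect_error(venn_partition(stats::setNames(list("x", "y"), c("A", "A"))),
               "unique")
})

test_that("Venn partitions satisfy inclusion-exclusion and a bitmask oracle", {
  withr::local_seed(41)
  for (rep in 1:15) {
    universe <- sprintf("e%02d", 1:20)
    sets <- lapply(1:3, function(i) sample(universe, sample(0:15, 1)))
    names(sets) <- c("A", "B", "C")
    if (all(lengths(sets) == 0)) next
    vp <- venn_partition(sets)
    # regions are disjoint and cover the union
    members <- unlist(vp$regions, use.names = FALSE)
    expect_identical(anyDuplicated(members), 0L)
    expect_setequal(members, unique(unlist(sets)))
    # each input set is recovered as the union of the regions containing it
    for (lab in names(sets)) {
      covered <- unlist(vp$regions[grepl(lab, names(vp$regions))],
                        use.names = FALSE)
      expect_setequal(as.character(covered), unique(sets[[lab]]))
    }
    # bitmask oracle: region of each element
    for (e in unique(unlist(sets))) {
      mask <- vapply(sets, function(s) e %in% s, logical(1))
      expect_true(e %in% venn_region(vp, names(sets)[mask]))
    }
  }
})

test_that("the published exclusive-ISP table partitions as 4/20/3", {
  tab <- reference_pas_tables()$exclusive_isps_4h
  shared <- c("shared ISP 1", "shared ISP 2")
  sets <- lapply(split(tab$pathway, tab$procedure), function(s) c(s, shared))
  vp <- venn_partition(sets)
  expect_equal(unname(vp$counts[["ALPPS"]]), 4L)
  expect_equal(unname(vp$counts[["PVL"]]), 20L)
  expect_equal(unname(vp$counts[["transection"]]), 3L)
  expect_setequal(venn_region(vp, names(sets)), shared)
})

test_that("PAS ratios follow their identities", {
  tab <- tibble::tibble(pathway = c("p1", "p2", "p3"),
                        a = c(3, 0, 1), b = c(3, 2, 0))
  expect_equal(pas_ratio(tab, "p1", "a", "b"), 1)
  expect_equal(pas_ratio(tab, "p2", "a", "b"), 0)
  expect_warning(r <- pas_ratio(tab, "p3", "a", "b"), "undefined")
  expect_true(is.na(r))
  # reciprocal identity on random tables
  withr::local_seed(42)
  rt <- tibble::tibble(pathway = sprintf("p%d", 1:10),
                       a = rnorm(10), b = rnorm(10))
  for (p in rt$pathway) {
    expect_equal(pas_ratio(rt, p, "a", "b") * pas_ratio(rt, p, "b", "a"), 1,
                 tolerance = 1e-12)
  }
})

test_that("the hypoxia EMT branch is 8.2-fold higher under ALPPS", {
  tab <- reference_pas_tables()$hx68_vs_alpps_4h
  r <- pas_ratio(tab, "Hypoxia pathway EMT 1", "pas_alpps", "pas_hx68")
  expect_equal(round(r, 1), 8.2)
})

test_that("identical columns merge first in average-linkage clustering", {
  m <- cbind(s1 = c(1, 2, 3, 4), s2 = c(4, 1, 2, 9), s3 = c(4, 1, 2, 9))
  hc <- hierarchical_cluster(m, metric = "euclidean")
  expect_setequal(hc$labels[-hc$merge[1, ]], c("s2", "s3"))
  expect_equal(hc$height[1], 0)
  expect_error(hierarchical_cluster(m[, 1, drop = FALSE]), "at least 2")
})

test_that("Pearson distance is 0 on self and 2 on the negation", {
  withr::local_seed(43)
  v <- rnorm(10)
  m <- cbind(a = v, b = v, c = -v)
  hc <- hierarchical_cluster(m, metric = "pearson")
  d <- as.matrix(stats::cophenetic(hc))
  expect_equal(hc$height[1], 0, tolerance = 1e-12) # a and b merge at 0
  expect_equal(unname(d["a", "c"]), 2, tolerance = 1e-12)
})

test_that("merge heights match a brute-force UPGMA oracle", {
  withr::local_seed(44)
  for (rep in 1:10) {
    m <- matrix(rnorm(40), 8, 5,
                dimnames = list(NULL, sprintf("s%d", 1:5)))
    for (metric in c("euclidean", "pearson")) {
      hc <- hierarchical_cluster(m, metric = metric)
      d <- if (metric == "euclidean") stats::dist(t(m))
           else stats::as.dist(1 - stats::cor(m))
      expect_equal(sort(hc$height), brute_upgma_heights(d),
                   tolerance = 1e-10)
    }
  }
})

test_that("constant columns get maximum Pearson distance with a note", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
  expect_message(hc <- hierarchical_cluster(m, metric = "pearson"),
                 "constant")
  d <- as.matrix(stats::cophenetic(hc))
  expect_gte(unname(d["a", "b"]), 1)
})

test_that("PCA captures collinear samples on one component", {
  base <- c(1, 2, 3, 4)
  m <- cbind(s1 = 0 * base, s2 = 1 * base, s3 = 2.5 * base, s4 = -1 * base)
  pc <- pca_transform(m, 2)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-12)
  # duplicated samples get identical coordinates
  m2 <- cbind(m, s5 = m[, "s2"])
  pc2 <- pca_transform(m2, 2)
  co <- pc2$coordinates
  expect_equal(unlist(co[co$sample == "s5", -1]),
               unlist(co[co$sample == "s2", -1]), tolerance = 1e-12)
  expect_error(pca_transform(m, 10), "n_components")
})

test_that("full-rank PCA reconstructs the centered input", {
  withr::local_seed(45)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  k <- min(dim(m))
  pc <- pca_transform(m, k)
  scores <- as.matrix(pc$coordinates[, -1])
  recon <- scores %*% t(pc$rotation)
  centered <- t(m) - matrix(pc$center, ncol(m), nrow(m), byrow = TRUE)
  expect_equal(unname(recon[, rownames(m)]), unname(centered),
               tolerance = 1e-9)
  # variance fractions are non-increasing and sum to at most 1
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  withr::local_seed(46)
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(NULL, sprintf("s%d", 1:5)))
  cc <- correlation_matrix(m, order = FALSE)
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_equal(cc, t(cc))
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  # textbook covariance-formula oracle
  oracle <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    x <- m[, i] - mean(m[, i])
    y <- m[, j] - mean(m[, j])
    oracle[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  expect_equal(unname(cc), oracle, tolerance = 1e-12)
  # negation correlates at -1
  m2 <- cbind(a = m[, 1], b = -m[, 1])
  expect_equal(unname(correlation_matrix(m2, order = FALSE)["a", "b"]), -1,
               tolerance = 1e-12)
  # constant vector handled with a warning
  m3 <- cbind(a = m[, 1], b = rep(2, 10))
  expect_warning(c3 <- correlation_matrix(m3, order = FALSE), "constant")
  expect_equal(unname(c3["a", "b"]), 0)
})

test_that("time profiles aggregate group PAS per (procedure, timepoint)", {
  des <- design_grid(procedures = c("sham", "ALPPS"), timepoints = c(1, 4),
                     replicates = 2)
  pas <- matrix(seq_len(2 * nrow(des)), 2, nrow(des),
                dimnames = list(c("p1", "p2"), des$sample_id))
  tp <- time_profiles(pas, des)
  expect_equal(nrow(tp), 2 * 4)
  cell <- tp[tp$pathway == "p1" & tp$procedure == "ALPPS" &
               tp$timepoint_h == 1, ]
  ids <- des$sample_id[des$procedure == "ALPPS" & des$timepoint_h == 1]
  expect_equal(cell$group_pas, mean(pas["p1", ids]))
  # timepoints strictly increasing within each procedure block
  for (pr in unique(tp$procedure)) {
    tt <- unique(tp$timepoint_h[tp$procedure == pr])
    expect_true(all(diff(tt) > 0))
  }
})
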