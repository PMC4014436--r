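# RBH orthology and synteny-cluster detection.

fake_hits <- function(q, s, bits, ev = 1e-20) {
  data.frame(query_id = q, subject_id = s, evalue = ev,
             percent_identity = 50, n_identical = 50,
             alignment_length = 100, bitscore = bits,
             query_length = 100, subject_length = 100, score = NA_real_,
             stringsAsFactors = FALSE)
}

order_table <- function(ids, contig = "c1") {
  data.frame(gene_id = ids, contig = contig, index = seq_along(ids),
             stringsAsFactors = FALSE)
}

test_that("RBH keeps only mutual best hits", {
  ab <- fake_hits(c("a1", "a2"), c("b1", "b2"), c(100, 90))
  ba <- fake_hits(c("b1", "b2"), c("a1", "a1"), c(100, 95))
  rbh <- rbh_orthologs(ab, ba)
  expect_equal(rbh$gene_a, "a1")  # b2's best is a1, so a2-b2 is not mutual
  expect_equal(rbh$gene_b, "b1")
  expect_equal(nrow(rbh_orthologs(ab[0, ], ba[0, ])), 0)
})

test_that("RBH agrees with a brute-force mutual-best oracle on random tables", {
  set.seed(81)
  for (rep in 1:10) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    a_ids <- sprintf("a%02d", 1:na); b_ids <- sprintf("b%02d", 1:nb)
    grid <- expand.grid(q = a_ids, s = b_ids, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < 0.4
    if (!any(keep)) next
    bits <- sample(10:500, sum(keep), replace = TRUE)
    ab <- fake_hits(grid$q[keep], grid$s[keep], bits)
    ba <- fake_hits(grid$s[keep], grid$q[keep], bits)
    rbh <- rbh_orthologs(ab, ba)
    # oracle: mutual argmax with the same tie-breaks
    best <- function(hits, q) {
      h <- hits[hits$query_id == q, ]
      if (!nrow(h)) return(NA_character_)
      h <- h[order(-h$bitscore, h$evalue, h$subject_id), ]
      h$subject_id[1]
    }
    expected <- character(0)
    for (a in a_ids) {
      b <- best(ab, a)
      if (!is.na(b) && identical(best(ba, b), a)) {
        expected <- c(expected, paste(a, b))
      }
    }
    expect_setequal(paste(rbh$gene_a, rbh$gene_b), expected)
    # RBH property: each gene at most once
    expect_equal(anyDuplicated(rbh$gene_a), 0)
    expect_equal(anyDuplicated(rbh$gene_b), 0)
  }
})

test_that("identical gene order yields a single full-length cluster", {
  ids_a <- sprintf("a%02d", 1:10); ids_b <- sprintf("b%02d", 1:10)
  orth <- data.frame(gene_a = ids_a, gene_b = ids_b, bitscore = 100)
  cl <- find_clusters(orth, order_table(ids_a), order_table(ids_b))
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(nrow(cl), 10)
  expect_equal(unique(cl$orientation), "+")
})

test_that("a reversed genome yields one inverted cluster", {
  ids_a <- sprintf("a%02d", 1:10); ids_b <- sprintf("b%02d", 1:10)
  orth <- data.frame(gene_a = ids_a, gene_b = ids_b, bitscore = 100)
  cl <- find_clusters(orth, order_table(ids_a), order_table(rev(ids_b)))
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(nrow(cl), 10)
  expect_equal(unique(cl$orientation), "-")
})

test_that("the 4-gene toy with a local swap clusters only the colinear pair", {
  ids_a <- c("a1", "a2", "a3", "a4")
  # on B the orthologs of a3 and a4 are swapped
  orth <- data.frame(gene_a = ids_a, gene_b = c("b1", "b2", "b3", "b4"),
                     bitscore = 100)
  gob <- order_table(c("b1", "b2", "b4", "b3"))
  cl <- find_clusters(orth, order_table(ids_a), gob,
                      max_gap = 0, min_cluster_size = 2)
  expect_setequal(cl$gene_a, c("a1", "a2"))
  expect_equal(unique(cl$orientation), "+")
})

test_that("gap tolerance is respected and monotone", {
  # anchors at A positions 1,2,6 / B positions 1,2,6: gap of 3 genes
  ids_a <- sprintf("a%d", 1:6); ids_b <- sprintf("b%d", 1:6)
  orth <- data.frame(gene_a = c("a1", "a2", "a6"),
                     gene_b = c("b1", "b2", "b6"), bitscore = 100)
  goa <- order_table(ids_a); gob <- order_table(ids_b)
  cl2 <- find_clusters(orth, goa, gob, max_gap = 2)
  expect_setequal(cl2$gene_a, c("a1", "a2"))
  cl3 <- find_clusters(orth, goa, gob, max_gap = 3)
  expect_setequal(cl3$gene_a, c("a1", "a2", "a6"))
  expect_gte(nrow(cl3), nrow(cl2))
  expect_error(find_clusters(orth, goa[-6, ], gob), "missing")
})

test_that("clusters are colinear and anchors belong to at most one cluster", {
  set.seed(82)
  for (rep in 1:8) {
    n <- 30
    ids_a <- sprintf("a%02d", 1:n)
    perm <- sample(n)
    ids_b <- sprintf("b%02d", 1:n)
    orth <- data.frame(gene_a = ids_a, gene_b = ids_b[perm],
                       bitscore = 100)
    cl <- find_clusters(orth, order_table(ids_a),
                        order_table(ids_b[order(perm)]))
    if (!nrow(cl)) next
    expect_equal(anyDuplicated(cl$gene_a), 0)
    for (cid in unique(cl$cluster_id)) {
      sub <- cl[cl$cluster_id == cid, ]
      da <- diff(sub$index_a); db <- diff(sub$index_b)
      expect_true(all(da >= 1 & da <= 3))  # max_gap 2
      expect_true(all(db >= 1 & db <= 3) || all(db <= -1 & db >= -3))
    }
  }
})

test_that("self-comparison of a genome clusters every gene, one cluster per contig", {
  spec <- genome_spec(n_contigs = 2, contig_length_mean = 30000,
                      contig_length_sd = 0, target_gene_density = 0.4,
                      seed = 9)
  g <- generate_genome(spec)
  go_a <- gene_order(g)
  go_b <- go_a
  go_b$gene_id <- paste0("B_", go_b$gene_id)
  orth <- data.frame(gene_a = go_a$gene_id,
                     gene_b = paste0("B_", go_a$gene_id), bitscore = 100)
  cl <- find_clusters(orth, go_a, go_b)
  expect_equal(length(unique(cl$cluster_id)),
               length(unique(go_a$contig)))
  expect_setequal(cl$gene_a, go_a$gene_id)
  fr <- synteny_fraction(cl, go_a$gene_id)
  expect_equal(fr$fraction, 1.0)
})

test_that("synteny fractions count clustered genes over the selection", {
  ids_a <- sprintf("a%02d", 1:10)
  cl <- data.frame(cluster_id = "S001", gene_a = ids_a[1:3],
                   gene_b = sprintf("b%02d", 1:3), contig_a = "c1",
                   contig_b = "d1", orientation = "+",
                   index_a = 1:3, index_b = 1:3)
  fr <- synteny_fraction(cl, ids_a)
  expect_equal(fr$fraction, 0.30)
  expect_equal(fr$n_clustered, 3)
  # without any ortholog, the fraction is zero
  fr0 <- synteny_fraction(cl[0, ], ids_a)
  expect_equal(fr0$fraction, 0)
  # the alternative denominator counts only orthologous genes
  orth <- data.frame(gene_a = ids_a[1:5], gene_b = sprintf("b%02d", 1:5),
                     bitscore = 100)
  fr2 <- synteny_fraction(cl, ids_a, orthologs = orth)
  expect_equal(fr2$fraction_of_orthologous, 3 / 5)
  expect_error(synteny_fraction(cl, character(0)), "non-empty")
})

test_that("largest_contigs ranks by length", {
  g <- structure(list(
    contigs = c(small = "AC", big = strrep("A", 100),
                mid = strrep("G", 10)),
    genes = data.frame(), exons = data.frame()),
    class = "annotated_genome")
  expect_equal(largest_contigs(g, 2), c("big", "mid"))
})
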