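# Network construction, components and representation calls.

make_hit <- function(q, s, evalue = 1e-12, pid = 25, n_id = 30,
                     len = 50, qlen = 100, slen = 100) {
  data.frame(query_id = q, subject_id = s, evalue = evalue,
             percent_identity = pid, n_identical = n_id,
             alignment_length = len, bitscore = 80,
             query_length = qlen, subject_length = slen, score = NA_real_,
             stringsAsFactors = FALSE)
}

no_hits <- function() make_hit("q", "s")[0, ]

test_that("the reciprocal edge test applies all four criteria strictly/inclusively", {
  crit <- edge_criteria()
  fwd <- make_hit("a", "b")
  rev <- make_hit("b", "a")
  expect_true(edge_test(fwd, rev, crit))

  # one failing direction kills the edge
  rev_bad <- make_hit("b", "a", evalue = 1e-9)
  expect_false(edge_test(fwd, rev_bad, crit))

  # boundary grid: identity exactly 20 fails, length exactly 20 fails,
  # identical fraction exactly 0.20 passes
  expect_false(edge_test(make_hit("a", "b", pid = 20),
                         make_hit("b", "a", pid = 20), crit))
  expect_false(edge_test(make_hit("a", "b", len = 20),
                         make_hit("b", "a", len = 20), crit))
  expect_true(edge_test(make_hit("a", "b", n_id = 20, qlen = 100,
                                 slen = 120),
                        make_hit("b", "a", n_id = 20, qlen = 120,
                                 slen = 100), crit))
  expect_false(edge_test(make_hit("a", "b", n_id = 19),
                         make_hit("b", "a", n_id = 19), crit))
  expect_false(edge_test(make_hit("a", "b", evalue = 1e-10),
                         make_hit("b", "a", evalue = 1e-10), crit))

  expect_error(edge_test(make_hit("a", "b"), make_hit("c", "a")),
               "directions")
})

test_that("relaxing any single criterion never shrinks the edge set", {
  set.seed(21)
  hits_list <- lapply(1:40, function(i) {
    q <- sample(letters[1:6], 1); s <- sample(setdiff(letters[1:6], q), 1)
    make_hit(q, s, evalue = 10^-runif(1, 5, 15),
             pid = runif(1, 10, 40), n_id = sample(10:40, 1),
             len = sample(10:60, 1))
  })
  hits <- do.call(rbind, hits_list)
  edge_count <- function(crit) {
    igraph::ecount(build_network(hits, proteins = letters[1:6],
                                 criteria = crit))
  }
  base <- edge_criteria()
  n0 <- edge_count(base)
  expect_gte(edge_count(edge_criteria(max_evalue = 1e-8)), n0)
  expect_gte(edge_count(edge_criteria(min_percent_identity = 15)), n0)
  expect_gte(edge_count(edge_criteria(min_identical_fraction = 0.1)), n0)
  expect_gte(edge_count(edge_criteria(min_alignment_length = 10)), n0)
})

test_that("networks include isolated vertices and identical proteins form cliques", {
  g <- build_network(no_hits(), proteins = letters[1:5])
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 0)

  seqs <- setNames(rep(random_protein(80), 4), c("p1", "p2", "p3", "p4"))
  set.seed(13)
  prot <- list(T1 = seqs[1:2], T2 = seqs[3:4])
  hits <- all_vs_all(prot)
  g <- build_network(hits)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 6)  # K4
})

test_that("components agree with a transitive-closure oracle on random graphs", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(5:50, 1)
    vertices <- sprintf("v%02d", seq_len(n))
    n_edges <- sample(0:(2 * n), 1)
    edges <- unique(t(replicate(n_edges, sort(sample(vertices, 2)))))
    if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2)
    hits <- do.call(rbind, c(
      list(no_hits()),
      lapply(seq_len(nrow(edges)), function(r) {
        rbind(make_hit(edges[r, 1], edges[r, 2]),
              make_hit(edges[r, 2], edges[r, 1]))
      })))
    g <- build_network(hits, proteins = vertices)
    fc <- connected_components(g)
    got <- lapply(split(fc$membership$protein_id,
                        fc$membership$component_id), sort)
    want <- components_oracle(vertices, edges)
    expect_setequal(lapply(unname(got), paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # partition property
    expect_setequal(fc$membership$protein_id, vertices)
    expect_equal(sum(fc$components$size), n)
    # ordering: decreasing size, ties by smallest member
    sizes <- fc$components$size
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("toy component shapes come out as expected", {
  hits <- rbind(make_hit("a", "b"), make_hit("b", "a"),
                make_hit("b", "c"), make_hit("c", "b"),
                make_hit("d", "e"), make_hit("e", "d"))
  fc <- connected_components(build_network(hits,
                                           proteins = letters[1:5]))
  got <- lapply(split(fc$membership$protein_id,
                      fc$membership$component_id), sort)
  expect_setequal(vapply(got, paste, collapse = ",", ""),
                  c("a,b,c", "d,e"))
})

test_that("representation calls follow the contracted/expanded/absent definitions", {
  counts_to_call <- function(f, c1, c2) {
    memb <- data.frame(
      protein_id = sprintf("p%d", seq_len(f + c1 + c2)),
      taxon = rep(c("focal", "comp1", "comp2"), c(f, c1, c2)))
    taxa <- setNames(memb$taxon, memb$protein_id)
    hits <- do.call(rbind, c(
      list(no_hits()),
      unlist(lapply(seq_len(nrow(memb)), function(i)
        lapply(seq_len(i - 1L), function(j)
          rbind(make_hit(memb$protein_id[i], memb$protein_id[j]),
                make_hit(memb$protein_id[j], memb$protein_id[i])))),
        recursive = FALSE)))
    g <- build_network(hits, proteins = memb$protein_id, taxa = taxa)
    fc <- connected_components(g, taxa = taxa)
    cl <- classify_components(fc, "focal", c("comp1", "comp2"))
    cl$components$representation_call[1]
  }
  expect_equal(counts_to_call(1, 3, 2), "contracted")
  expect_equal(counts_to_call(14, 2, 1), "expanded")
  expect_equal(counts_to_call(2, 2, 2), "balanced")
  expect_equal(counts_to_call(3, 2, 2), "expanded")
  expect_equal(counts_to_call(2, 2, 3), "balanced")
})

test_that("absent-in-focal components are called and unknown taxa rejected", {
  memb <- data.frame(protein_id = c("x1", "x2", "x3", "x4"),
                     taxon = c("comp1", "comp1", "comp2", "comp2"))
  taxa <- setNames(memb$taxon, memb$protein_id)
  hits <- do.call(rbind, unlist(
    lapply(seq_len(4), function(i) lapply(seq_len(i - 1L), function(j)
      rbind(make_hit(memb$protein_id[i], memb$protein_id[j]),
            make_hit(memb$protein_id[j], memb$protein_id[i])))),
    recursive = FALSE))
  fc <- connected_components(build_network(hits, proteins = memb$protein_id,
                                           taxa = taxa), taxa = taxa)
  # focal taxon exists in the study but has no members in this component
  fc$taxa <- c(fc$taxa, "focal")
  fc$components$n_focal <- 0L
  cl <- classify_components(fc, "focal", c("comp1", "comp2"))
  expect_equal(cl$components$representation_call, "absent-in-focal")
  expect_error(classify_components(fc, "nosuch", "comp1"), "unknown taxon")
})

test_that("category summaries use majority vote with ambiguous/unknown fallbacks", {
  fx <- contraction_fixture()
  g <- build_network(fx$hits)
  fc <- connected_components(g)
  cl <- classify_components(fc, "focal", c("comparator1", "comparator2"))
  ann <- contraction_study_annotation(fx$truth, fx$specs)
  summ <- summarize_categories(cl, ann)
  tab <- summ$table
  contracted <- tab[tab$representation_call == "contracted", ]
  # ledger: 10 contracted families in 3 categories (4/3/3)
  expect_setequal(contracted$category,
                  c("transport", "translation", "chromatin"))
  expect_equal(sum(contracted$n_components), 10)
  expect_equal(contracted$n_components[order(contracted$category)],
               c(3L, 3L, 4L))  # chromatin, translation, transport

  # majority / tie / unannotated rules on a hand-built component
  memb <- data.frame(protein_id = c("m1", "m2", "m3"),
                     taxon = c("focal", "comp1", "comp2"))
  taxa <- setNames(memb$taxon, memb$protein_id)
  hits <- rbind(make_hit("m1", "m2"), make_hit("m2", "m1"),
                make_hit("m2", "m3"), make_hit("m3", "m2"))
  cl2 <- classify_components(
    connected_components(build_network(hits, proteins = memb$protein_id,
                                       taxa = taxa), taxa = taxa),
    "focal", c("comp1", "comp2"))
  expect_equal(summarize_categories(
    cl2, c(m1 = "A", m2 = "A", m3 = "B"))$component_categories$category,
    "A")
  expect_equal(summarize_categories(
    cl2, c(m1 = "A", m2 = "B"))$component_categories$category,
    "ambiguous")
  expect_equal(summarize_categories(
    cl2, c(zz = "A"))$component_categories$category, "unknown")
  # category blacklist drops components from the table
  excl <- summarize_categories(cl2, c(m1 = "A", m2 = "A"),
                               exclude_categories = "A")
  expect_equal(nrow(excl$table), 0)
})

test_that("contracted/expanded calls recover the planted ledger perfectly", {
  fx <- contraction_fixture()
  g <- build_network(fx$hits)
  fc <- connected_components(g)
  cl <- classify_components(fc, "focal", c("comparator1", "comparator2"))

  # components must be exactly the planted families
  memb <- merge(cl$membership, fx$truth$memberships, by = "protein_id")
  cross <- table(memb$component_id, memb$family_id)
  expect_true(all(rowSums(cross > 0) == 1))
  expect_true(all(colSums(cross > 0) == 1))

  # calls: perfect precision and recall of the contracted label
  fam_of <- setNames(fx$truth$memberships$family_id,
                     fx$truth$memberships$protein_id)
  comp_family <- vapply(split(cl$membership$protein_id,
                              cl$membership$component_id),
                        function(p) unname(fam_of[p[1]]), "")
  truth_call <- setNames(fx$truth$families$expected_call,
                         fx$truth$families$family_id)
  got_call <- setNames(cl$components$representation_call,
                       cl$components$component_id)
  aligned_truth <- unname(truth_call[comp_family[names(got_call)]])
  # multi-member families are fully recovered; absent-in-focal families
  # have no focal member, so components exist only for comparator copies
  expect_equal(unname(got_call), aligned_truth)
  for (target in c("contracted", "expanded")) {
    tp <- sum(got_call == target & aligned_truth == target)
    expect_equal(tp / sum(got_call == target), 1.0)      # precision
    expect_equal(tp / sum(aligned_truth == target), 1.0) # recall
  }
})
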