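test_that("subgraph search enumerates embeddings like brute force", {
  eth <- fix_ethanol()
  expect_length(subgraph_search(mk_mol("C"), eth), 2L)
  expect_length(subgraph_search(mk_mol(c("C", "C", "O"), path_bonds(3)), eth), 1L)

  # self-embedding always contains the identity
  for (seed in 1:5) {
    m <- random_small_mol(5L, id = "self")
    keys <- match_keys(subgraph_search(m, m))
    id_key <- paste(sprintf("%d:%d", 1:5, 1:5), collapse = ",")
    expect_true(id_key %in% keys)
  }

  with_seed(77, {
    for (rep in 1:40) {
      target <- random_small_mol(sample(4:8, 1), id = "t")
      pattern <- random_small_mol(sample(2:5, 1), id = "p")
      for (strict in c(TRUE, FALSE)) {
        got <- match_keys(subgraph_search(pattern, target, order_strict = strict))
        want <- oracle_embeddings(pattern, target, order_strict = strict)
        expect_identical(got, want)
      }
    }
  })
})

test_that("every returned mapping is injective and label/bond preserving", {
  with_seed(12, {
    for (rep in 1:15) {
      target <- random_small_mol(7L, id = "t")
      pattern <- random_small_mol(3L, id = "p")
      for (h in subgraph_search(pattern, target)) {
        expect_false(anyDuplicated(h$mapping$target) > 0)
        expect_equal(pattern$atoms$element[h$mapping$pattern],
                     target$atoms$element[h$mapping$target])
        for (k in seq_len(nrow(pattern$bonds))) {
          i <- h$mapping$target[match(pattern$bonds$a[k], h$mapping$pattern)]
          j <- h$mapping$target[match(pattern$bonds$b[k], h$mapping$pattern)]
          tb <- metharmonize:::bond_between(target, i, j)
          expect_length(tb, 1L)
          expect_equal(target$bonds$order[tb], pattern$bonds$order[k])
        }
      }
    }
  })
})

test_that("graph isomorphism distinguishes constitutional isomers", {
  expect_null(graph_isomorphism(fix_butane(), fix_isobutane()))
  m <- random_small_mol(6L, id = "iso")
  expect_false(is.null(graph_isomorphism(m, m)))
  p <- permute_molecule(m)
  expect_false(is.null(graph_isomorphism(m, p)))
})

test_that("graph isomorphism agrees with an independent igraph check", {
  skip_if_not_installed("igraph")
  to_ig <- function(m) {
    g <- igraph::graph_from_data_frame(m$bonds[, c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(nrow(m$atoms))))
    igraph::V(g)$color <- as.integer(factor(m$atoms$element, levels = c("C", "N", "O", "S")))
    igraph::E(g)$ecol <- as.integer(factor(m$bonds$order, levels = c("1", "2", "3", "a")))
    g
  }
  with_seed(5, {
    for (rep in 1:20) {
      a <- random_small_mol(6L, id = "a")
      b <- if (rep %% 2L == 0L) permute_molecule(a) else random_small_mol(6L, id = "b")
      ga <- to_ig(a); gb <- to_ig(b)
      want <- igraph::is_isomorphic_to(
        ga, gb, method = "vf2",
        vertex.color1 = igraph::V(ga)$color, vertex.color2 = igraph::V(gb)$color,
        edge.color1 = igraph::E(ga)$ecol, edge.color2 = igraph::E(gb)$ecol
      )
      expect_equal(!is.null(graph_isomorphism(a, b)), want)
    }
  })
})

test_that("maximum common subgraph finds the exhaustive optimum", {
  m <- random_small_mol(5L, id = "mcs")
  full <- maximum_common_subgraph(m, m)
  expect_equal(nrow(full$mapping), 5L)

  ethylamine <- mk_mol(c("C", "C", "N"), path_bonds(3))
  got <- maximum_common_subgraph(fix_ethanol(), ethylamine)
  expect_equal(nrow(got$mapping), 2L)
  expect_equal(fix_ethanol()$atoms$element[got$mapping$pattern], c("C", "C"))

  with_seed(99, {
    for (rep in 1:12) {
      a <- random_small_mol(sample(3:5, 1), id = "a")
      b <- random_small_mol(sample(4:6, 1), id = "b")
      got <- maximum_common_subgraph(a, b)
      want <- oracle_mcs_size(a, b)
      if (is.null(got)) {
        expect_equal(want[1], 0L)
      } else {
        expect_equal(nrow(got$mapping), want[1])
        expect_equal(nrow(got$matched_bonds), want[2])
      }
    }
  })
})

test_that("anchored MCS honours and validates its seed", {
  a <- fix_ethanol(); b <- mk_mol(c("C", "C", "O"), path_bonds(3), id = "b")
  anchored <- maximum_common_subgraph(a, b, anchors = data.frame(pattern = 1L, target = 1L))
  expect_true(any(anchored$mapping$pattern == 1L & anchored$mapping$target == 1L))
  expect_error(
    maximum_common_subgraph(a, b, anchors = data.frame(pattern = 1L, target = 3L)),
    class = "mh_precondition_error"
  )
})

test_that("R pattern atoms match any heavy atom unless ignored", {
  pat <- mk_mol(c("R", "C"), path_bonds(2))
  tgt <- mk_mol(c("O", "C", "N"), path_bonds(3))
  hits <- subgraph_search(pat, tgt)
  expect_length(hits, 2L)   # R stands on either heavy neighbor of the carbon
  hits_ign <- subgraph_search(pat, tgt, ignore_r_h = TRUE)
  expect_length(hits_ign, 1L)  # bare C pattern, one carbon in the target
})
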