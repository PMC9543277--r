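test_that("cell networks keep exactly the co-present documented edges", {
  tb <- interaction_table(c("a", "a"), c("c", "d"))
  pm <- presence_from_list(list(cell1 = c("a", "c"),
                                cell2 = c("a", "b"),
                                cell3 = c("a", "c", "d")),
                           all_species = c("a", "b", "c", "d"))
  net1 <- cell_network("cell1", pm, tb)
  expect_equal(net1$edges$host, "c")
  expect_equal(net1$n_species, 2)
  # parasite present without hosts: empty network
  net2 <- cell_network("cell2", pm, tb)
  expect_equal(net2$n_interactions, 0)
  expect_equal(classify_topology(net2), "empty")
  # all species present: the global table
  net3 <- cell_network("cell3", pm, tb)
  expect_equal(nrow(net3$edges), 2)
  expect_error(cell_network("nope", pm, tb), "unknown cell")
})

test_that("cell networks match a brute-force edge filter on random fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    tb <- random_network(6, 9)
    species <- union(tb$parasites, tb$hosts)
    cells <- lapply(1:6, function(i) {
      sample(species, sample.int(length(species), 1))
    })
    names(cells) <- paste0("c", 1:6)
    pm <- presence_from_list(cells, all_species = species)
    for (cid in names(cells)) {
      net <- cell_network(cid, pm, tb)
      manual <- tb$edges[tb$edges$parasite %in% cells[[cid]] &
                           tb$edges$host %in% cells[[cid]], ]
      expect_equal(nrow(net$edges), nrow(manual))
      expect_setequal(paste(net$edges$parasite, net$edges$host),
                      paste(manual$parasite, manual$host))
    }
  }
})

test_that("the worked linkage-density values 0.5, 1.0 and 2.8 are reproduced", {
  one <- new_network_from_edges("p1", "h1")
  expect_equal(linkage_density(one), 0.5)

  full22 <- new_network_from_edges(rep(c("p1", "p2"), each = 2),
                                   rep(c("h1", "h2"), 2))
  expect_equal(linkage_density(full22), 1.0)

  big <- max_complexity_network()
  expect_equal(big$n_interactions, 241)
  expect_length(big$parasite_nodes, 6)
  expect_length(big$host_nodes, 80)
  expect_equal(round(linkage_density(big), 1), 2.8)
})

test_that("empty networks have no linkage density", {
  tb <- interaction_table("a", "c")
  pm <- presence_from_list(list(c1 = "a"), all_species = c("a", "c"))
  expect_error(linkage_density(cell_network("c1", pm, tb)), "undefined")
})

test_that("topology classes follow the parasite/host node counts", {
  expect_equal(classify_topology(new_network_from_edges("a", "c")), "one_to_one")
  expect_equal(classify_topology(new_network_from_edges(c("a", "a"), c("c", "d"))),
               "one_to_many")
  expect_equal(classify_topology(new_network_from_edges(c("a", "b"), c("c", "c"))),
               "many_to_one")
  # two disjoint pairs: many_to_many at whole-network level...
  disj <- new_network_from_edges(c("a", "b"), c("c", "d"))
  expect_equal(classify_topology(disj), "many_to_many")
  # ...but two one-to-one components in the diagnostic breakdown
  expect_equal(component_topologies(disj), c("one_to_one", "one_to_one"))
})

test_that("linkage density is at least 0.5 and invariant to relabeling", {
  set.seed(13)
  for (rep in 1:50) {
    tb <- random_network()
    net <- global_network_of(tb)
    ld <- linkage_density(net)
    expect_gte(ld, 0.5)
    if (net$n_interactions == 1L) expect_equal(ld, 0.5)
    relab <- interaction_table(paste0("zz_", tb$edges$parasite),
                               paste0("qq_", tb$edges$host))
    expect_equal(linkage_density(global_network_of(relab)), ld)
  }
})

test_that("adding edges moves linkage density as the weighted-average property predicts", {
  set.seed(17)
  for (rep in 1:20) {
    tb <- random_network(5, 8)
    net <- global_network_of(tb)
    ld <- linkage_density(net)
    # an edge between existing species strictly increases the density
    missing <- expand.grid(parasite = net$parasite_nodes,
                           host = net$host_nodes,
                           stringsAsFactors = FALSE)
    missing <- missing[!paste(missing$parasite, missing$host) %in%
                         paste(tb$edges$parasite, tb$edges$host), ]
    if (nrow(missing) > 0) {
      tb2 <- interaction_table(c(tb$edges$parasite, missing$parasite[1]),
                               c(tb$edges$host, missing$host[1]))
      expect_gt(linkage_density(global_network_of(tb2)), ld)
    }
    # an isolated fresh pair pulls the density towards 0.5
    tb3 <- interaction_table(c(tb$edges$parasite, "fresh_p"),
                             c(tb$edges$host, "fresh_h"))
    ld3 <- linkage_density(global_network_of(tb3))
    expect_equal(ld3, (net$n_interactions + 1) / (net$n_species + 2))
    if (ld > 0.5) expect_lt(ld3, ld) else expect_gte(ld3, ld)
  }
})

test_that("complexity tables assemble per-cell metrics and flag empty cells", {
  g <- build_planar_hex_grid(c(0, 30, 0, 30), 40)
  tb <- interaction_table(c("a", "a", "b"), c("c", "d", "c"))
  cells <- setNames(rep(list(character(0)), length(g$cell_id)), g$cell_id)
  cells[[g$cell_id[1]]] <- c("a", "c")
  pm <- presence_from_list(cells, all_species = c("a", "b", "c", "d"))
  ct <- complexity_table(g, pm, tb)
  expect_equal(sum(!is.na(ct$linkage_density)), 1)
  expect_equal(ct$topology_class[1], "one_to_one")
  expect_true(all(ct$topology_class[-1] == "empty"))
  expect_true(all(is.na(ct$linkage_density[-1])))
  # uniform composition -> constant column
  pm_all <- presence_everywhere(g$cell_id, c("a", "b", "c", "d"))
  ct_all <- complexity_table(g, pm_all, tb)
  expect_equal(unique(ct_all$linkage_density), 3 / 4)
  expect_true(all(ct_all$topology_class == "many_to_many"))
})

test_that("the complexity table matches per-cell networks computed one by one", {
  set.seed(41)
  tb <- random_network(6, 10)
  species <- union(tb$parasites, tb$hosts)
  g <- build_planar_hex_grid(c(0, 20, 0, 20), 30)
  cells <- lapply(g$cell_id, function(cid)
    sample(species, sample.int(length(species), 1)))
  names(cells) <- g$cell_id
  pm <- presence_from_list(cells, all_species = species)
  ct <- complexity_table(g, pm, tb)
  for (i in seq_along(g$cell_id)) {
    net <- cell_network(g$cell_id[i], pm, tb)
    expect_equal(ct$n_interactions[i], net$n_interactions)
    expect_equal(ct$n_species[i], net$n_species)
    expect_equal(ct$topology_class[i], classify_topology(net))
    if (net$n_interactions > 0) {
      expect_equal(ct$linkage_density[i], linkage_density(net))
    } else {
      expect_true(is.na(ct$linkage_density[i]))
    }
  }
})

test_that("the three-cell worked fixture yields the 0.5 / 1.0 / 2.8 column", {
  ct <- worked_fixture_complexity()
  ids <- attr(ct, "worked_cells")
  expect_equal(ct$linkage_density_1dp[match(ids, ct$cell_id)],
               c(0.5, 1.0, 2.8))
})
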