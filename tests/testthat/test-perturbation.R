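at_net <- circuit_fixture("at_direct")
sl_net <- circuit_fixture("sl_direct")

test_that("path signs multiply along simple paths", {
  # SlARF18 -| SlDREB26 -| SlNLP7B -> SlNIR1: (-)(-)(+) = +
  expect_equal(net_path_sign(sl_net, "SlARF18", "SlNIR1"), "positive")
  # the Arabidopsis DREB26 has no direct route to the reductase
  expect_equal(net_path_sign(at_net, "AtDREB26", "AtNIR1"), "none")
  # ANAC032 reaches NIR1 directly (-) and via NLP7 (-)(+): all negative
  expect_equal(net_path_sign(at_net, "AtANAC032", "AtNIR1"), "negative")
  # conflicting routes are mixed
  e <- data.frame(source = c("X", "X", "Y"), target = c("Z", "Y", "Z"),
                  sign = c("activating", "repressing", "activating"),
                  mode = "direct", evidence = "target_direct")
  expect_equal(net_path_sign(build_network(e), "X", "Z"), "mixed")
  # unknown sign on a path contributes mixed
  e$sign[1] <- "unknown"
  expect_equal(net_path_sign(build_network(e), "X", "Z"), "mixed")
})

expected_at <- c(Atanac032 = "higher", Atarf9 = "unconnected",
                 Atarf18 = "lower", Atdreb26 = "unconnected",
                 Atnlp6 = "lower", Atnlp7 = "lower",
                 Atarf18_anac032 = "higher", Atanac032_nlp7 = "lower",
                 Atdreb26_nlp7 = "lower", Atarf18_nlp7 = "lower")
expected_sl <- c(Slarf9b = "lower", Slarf18 = "lower", Sldreb26 = "higher",
                 Slnlp7a = "lower", Slnlp7b = "lower",
                 Slarf9b_18 = "lower", Slarf9b_18_dreb26 = "higher",
                 Slnlp7a_7b = "lower", Sldreb26_nlp7a_7b = "lower",
                 Slarf9b_18_dreb26_nlp7a_7b = "lower")

test_that("fixture genotypes reproduce every stated prediction direction", {
  for (sp in c("At", "Sl")) {
    net <- if (sp == "At") at_net else sl_net
    expected <- if (sp == "At") expected_at else expected_sl
    px <- parot_genotypes(sp)
    for (geno in px$genotypes) {
      pred <- predict_genotype(net, geno)
      expect_equal(pred$direction, unname(expected[geno$label]),
                   info = geno$label)
      if (pred$direction %in% c("higher", "lower")) {
        expect_true(pred$dominant_node %in% geno$knocked_out)
      }
    }
  }
})

test_that("the downstream factor dominates higher-order knockouts", {
  # the repressor ANAC032 is downstream of ARF18, so the double knockout
  # inherits its raised-reporter phenotype
  p <- predict_genotype(at_net, genotype(c("AtARF18", "AtANAC032")))
  expect_equal(p$direction, "higher")
  expect_equal(p$dominant_node, "AtANAC032")
  # DREB26 dominates the tomato ARFs; the NLP pair dominates DREB26
  p2 <- predict_genotype(sl_net,
                         genotype(c("SlARF9B", "SlARF18", "SlDREB26")))
  expect_equal(p2$direction, "higher")
  expect_equal(p2$dominant_node, "SlDREB26")
  p3 <- predict_genotype(sl_net,
                         genotype(c("SlDREB26", "SlNLP7A", "SlNLP7B")))
  expect_equal(p3$direction, "lower")
  expect_true(p3$dominant_node %in% c("SlNLP7A", "SlNLP7B"))
})

test_that("wild type and invalid genotypes are handled", {
  expect_equal(predict_genotype(at_net, genotype(character(0)))$direction,
               "unchanged")
  expect_error(predict_genotype(at_net, genotype("AtFOO")),
               "absent from the network.*AtFOO")
})

test_that("a multi-knockout with one connected gene equals its single KO", {
  # DREB26 is unconnected in Arabidopsis, so pairing it with any connected
  # gene leaves that gene's single-knockout prediction unchanged
  for (g in c("AtANAC032", "AtNLP7", "AtARF18")) {
    single <- predict_genotype(at_net, genotype(g))
    multi <- predict_genotype(at_net, genotype(c(g, "AtDREB26")))
    expect_equal(multi$direction, single$direction, info = g)
  }
})

test_that("adding a dominated upstream knockout never changes the call", {
  for (sp in c("At", "Sl")) {
    net <- if (sp == "At") at_net else sl_net
    px <- parot_genotypes(sp)
    for (geno in px$genotypes) {
      base <- predict_genotype(net, geno)
      if (!(base$direction %in% c("higher", "lower"))) next
      upstream <- setdiff(net$nodes, c(geno$knocked_out,
                                       net$output_node))
      for (u in upstream) {
        aug <- predict_genotype(net, genotype(c(geno$knocked_out, u)))
        dom <- predict_genotype(net, genotype(u))
        # only assert when the added gene lies strictly upstream of the
        # existing dominant node
        g <- igraph::graph_from_data_frame(
          net$edges[net$edges$mode == "direct" &
                      net$edges$source != net$edges$target,
                    c("source", "target")],
          vertices = data.frame(name = net$nodes))
        reach_u <- names(igraph::subcomponent(g, u, mode = "out"))
        if (base$dominant_node %in% setdiff(reach_u, u)) {
          expect_equal(aug$direction, base$direction,
                       info = paste(geno$label, "+", u))
        }
      }
    }
  }
})

test_that("single-knockout calls agree with a brute-force truth table", {
  for (seed in 1:10) {
    gn <- gen_network(n_nodes = 8, n_edges = 10, n_planted_ffls = 1,
                      seed = seed)
    net <- gn$network
    out <- net$nodes[length(net$nodes)]
    net$output_node <- out
    e <- net$edges
    sgn <- function(s) c(activating = 1, repressing = -1)[s]
    # exhaustive DFS over simple paths, independent of the package's
    # enumeration
    paths_sign <- function(node) {
      res <- c()
      walk <- function(cur, visited, acc) {
        if (cur == out) { res <<- c(res, acc); return(invisible()) }
        nxt <- which(e$source == cur & !(e$target %in% visited))
        for (i in nxt) walk(e$target[i], c(visited, e$target[i]),
                            acc * sgn(e$sign[i]))
      }
      walk(node, node, 1)
      res
    }
    for (node in setdiff(net$nodes, out)) {
      ps <- paths_sign(node)
      want <- if (length(ps) == 0) "unconnected"
              else if (all(ps > 0)) "lower"
              else if (all(ps < 0)) "higher"
              else "indeterminate"
      got <- predict_genotype(net, genotype(node))$direction
      expect_equal(got, want, info = paste("seed", seed, "node", node))
    }
  }
})

test_that("prediction/observation concordance is scored correctly", {
  px <- parot_genotypes("At")
  preds <- lapply(px$genotypes, predict_genotype, net = at_net)
  rep <- compare_to_observations(preds, px$observations)
  expect_equal(unname(rep$summary["mismatch"]), 0L)
  expect_equal(unname(rep$summary["untestable"]), 2L)  # arf9, dreb26
  # constructed-identical observations give a full match
  obs <- data.frame(label = vapply(preds, function(p) p$genotype$label,
                                   character(1)),
                    observed_direction = vapply(preds, `[[`, character(1),
                                                "direction"))
  obs <- obs[!(obs$observed_direction %in%
                 c("unconnected", "indeterminate")), ]
  full <- compare_to_observations(preds, obs)
  expect_equal(unname(full$summary["match"]), nrow(obs))
  expect_equal(unname(full$summary["mismatch"]), 0L)
  # one flipped observation yields exactly one mismatch
  flip <- obs
  flip$observed_direction[1] <- ifelse(flip$observed_direction[1] == "lower",
                                       "higher", "lower")
  rep2 <- compare_to_observations(preds, flip)
  expect_equal(unname(rep2$summary["mismatch"]), 1L)
  # observed-but-unpredicted genotypes are flagged, not fatal
  extra <- rbind(obs, data.frame(label = "ghost",
                                 observed_direction = "lower"))
  expect_warning(rep3 <- compare_to_observations(preds, extra),
                 "without a prediction")
  expect_equal(unname(rep3$summary["unmatched"]), 1L)
})

test_that("dose-response direction extraction respects the threshold", {
  wt <- data.frame(nitrate_mM = rep(c(0, 1, 10), each = 4),
                   normalized_luminescence = rep(c(1, 3, 6), each = 4))
  lower <- wt; lower$normalized_luminescence <- wt$normalized_luminescence * 0.3
  higher <- wt; higher$normalized_luminescence <- wt$normalized_luminescence * 2
  flat <- wt; flat$normalized_luminescence <- wt$normalized_luminescence * 1.01
  expect_equal(direction_from_luminescence(lower, wt), "lower")
  expect_equal(direction_from_luminescence(higher, wt), "higher")
  expect_equal(direction_from_luminescence(flat, wt), "unchanged")
})
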