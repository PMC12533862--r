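# Builds a complete synthetic input bundle (screen table, pocket pose,
# MD replicate series, manifest, YAML config) under `dir`, returning the
# planted ground truth.
make_pipeline_bundle <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  scr <- makeScreen(100, 4, "top_bin", seed = seed)
  df <- compounds(scr$table)
  active <- df$id %in% scr$activeIds
  df$overlap <- ifelse(active, 0.9, 0.2)
  df$include <- active
  # score gate set at the worst active score: actives pass all three gates
  scoreThr <- max(df$score[active])
  utils::write.table(df, file.path(dir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fx <- makePocketFixture(9, 4, 5, seed = seed)
  writeLines(fx$receptorText, file.path(dir, "receptor.pdb"))
  writeLines(fx$ligandText, file.path(dir, "ligand.mol2"))

  mkseries <- function(tr, stem) {
    vapply(seq_along(tr$replicates), function(r) {
      p <- file.path(dir, sprintf("%s_rep%d.csv", stem, r))
      s <- tr$replicates[[r]]
      writeLines(sprintf("%.4f,%.5f", seriesTimes(s), seriesValues(s)), p)
      basename(p)
    }, character(1))
  }
  stab <- makeTrajectory("stable", mu = 1.5, sigma = 0.2, seed = seed)
  esc <- makeTrajectory("escaping", mu = 2, sigma = 0.2, crossTime = 4,
                        seed = seed + 1)
  man <- data.frame(compound = c("stays_bound", "escapes"),
                    rep1 = NA, rep2 = NA, rep3 = NA)
  man[1, 2:4] <- mkseries(stab, "stable")
  man[2, 2:4] <- mkseries(esc, "escape")
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg <- list(
    seed = seed, output_dir = "out",
    screen = list(table = "screen.tsv", fraction = 0.01,
                  score_threshold = scoreThr, overlap_threshold = 0.5,
                  require_clinical = TRUE),
    interaction = list(receptor = "receptor.pdb", ligand = "ligand.mol2"),
    md = list(manifest = "manifest.tsv", unit = "angstrom"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  list(config = file.path(dir, "config.yaml"), activeIds = scr$activeIds,
       expectedEF = scr$expectedEF, scoreThr = scoreThr)
}
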