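# SYNTHETIC stand-in for the study's occurrence database (the original
# supplementary file is not redistributable). Six species with known
# occupied-cell counts on the 2.5-arcminute continental grid; each
# occupied cell emits several jittered raw records, so thinning must
# recover exactly the designed per-cell counts.
synthetic_study_counts <- c(
  "Macrotermes bellicosus" = 147L,
  "Macrotermes falciger" = 79L,
  "Macrotermes muelleri" = 42L,
  "Macrotermes natalensis" = 247L,
  "Macrotermes subhyalinus" = 174L,
  "Macrotermes vitrialatus" = 45L)

make_synthetic_study_db <- function(path, seed = 20220152) {
  grid <- build_grid(-20, -35, 52, 38, 2.5)
  delta <- 2.5 / 60
  set.seed(seed)
  rows <- list()
  for (sp in names(synthetic_study_counts)) {
    n_cells <- synthetic_study_counts[[sp]]
    idx <- sample.int(grid$n_rows * grid$n_cols, n_cells)
    row <- (idx - 1) %/% grid$n_cols + 1
    col <- (idx - 1) %% grid$n_cols + 1
    reps <- sample(1:3, n_cells, replace = TRUE)
    row <- rep(row, reps)
    col <- rep(col, reps)
    lon <- grid$west + (col - 1 + runif(length(col), 0.01, 0.99)) * delta
    lat <- (grid$south + grid$n_rows * delta) -
      (row - 1 + runif(length(row), 0.01, 0.99)) * delta
    rows[[sp]] <- data.frame(species = sp, longitude = lon, latitude = lat)
  }
  db <- do.call(rbind, rows)
  db <- db[sample(nrow(db)), ]  # shuffle record order across species
  utils::write.csv(db, path, row.names = FALSE)
  invisible(grid)
}
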