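# shared fixtures, built in code

# write a toy genotype/phenotype pair of delimited files; returns the paths
write_toy_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                             sep = "\t", scramble = FALSE) {
  g <- data.frame(
    line_id = c("L1", "L2", "L3"),
    geneA = c(1, 0, 1),
    geneB = c(0, 1, 1)
  )
  p <- data.frame(
    line_id = c("L1", "L2", "L3"),
    growth = c(10, 20, 40)
  )
  if (scramble) p <- p[c(3, 1, 2), ]
  gp <- file.path(dir, "genotype.txt")
  pp <- file.path(dir, "phenotype.txt")
  write.table(g, gp, sep = sep, row.names = FALSE, quote = FALSE)
  write.table(p, pp, sep = sep, row.names = FALSE, quote = FALSE)
  list(genotype = gp, phenotype = pp, dir = dir)
}

# a decomposition object with prescribed components, for unit-level tests
fake_decomp <- function(U, d, V, k = length(d),
                        phenotype_names = paste0("p", seq_along(d))) {
  structure(
    list(
      U = U, d = d, V = V, var_frac = d^2 / sum(d^2),
      phenotype_names = phenotype_names, k = k
    ),
    class = "eigentrait_decomposition"
  )
}

# small normalized screen ready for scanning
prepared_screen <- function(G = 10, n_strong = 4, n_edges = 0, seed = 1, ...) {
  sim <- simulate_screen(G = G, n_strong = n_strong, n_edges = n_edges, seed = seed, ...)
  ds <- normalize_phenotypes(sim$dataset)
  dec <- select_eigentraits(decompose_phenotypes(ds))
  list(sim = sim, dataset = ds, decomp = dec)
}
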