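# shared fixtures and independent oracles

# hand-formatted PDB ATOM record (independent of the package's writer)
pdbAtomLine <- function(ser, name, res, chain, resno, x, y, z,
                        occ = 1, b = 0, elem = substr(name, 1, 1),
                        alt = " ", record = "ATOM  ") {
  name4 <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, ser, name4, alt, res, chain, resno, x, y, z, occ, b, elem)
}

# Gly-Ala-Gly tripeptide, 13 atoms, plausible extended geometry
gagPdbLines <- function() {
  res <- list(
    list("GLY", 1, rbind(N = c(0.0, 0.0, 0.0), CA = c(1.46, 0.0, 0.0),
                         C = c(2.0, 1.4, 0.0), O = c(1.3, 2.4, 0.0))),
    list("ALA", 2, rbind(N = c(3.3, 1.5, 0.0), CA = c(4.0, 2.8, 0.0),
                         C = c(5.5, 2.7, 0.0), O = c(6.1, 1.6, 0.0),
                         CB = c(3.6, 3.7, 1.2))),
    list("GLY", 3, rbind(N = c(6.2, 3.8, 0.0), CA = c(7.6, 3.9, 0.0),
                         C = c(8.3, 5.2, 0.0), O = c(7.7, 6.3, 0.0))))
  ser <- 0
  lines <- character()
  for (r in res) {
    xyz <- r[[3]]
    for (nm in rownames(xyz)) {
      ser <- ser + 1
      lines <- c(lines, pdbAtomLine(ser, nm, r[[1]], "A", r[[2]],
                                    xyz[nm, 1], xyz[nm, 2], xyz[nm, 3]))
    }
  }
  c(lines, "TER", "END")
}

writeGagPdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(gagPdbLines(), path)
  path
}

# bare-sphere structure for SASA oracle tests
sphereStructure <- function(centers, element = "C") {
  n <- nrow(centers)
  new("ProteinStructure", atoms = data.frame(
    chain = "A", resno = seq_len(n), code = "A", name = "CB",
    element = element, x = centers[, 1], y = centers[, 2],
    z = centers[, 3], occ = 1, stringsAsFactors = FALSE))
}

# Monte-Carlo surface-sampling SASA oracle: uniform random points on each
# expanded sphere, fraction outside all other expanded spheres
mcSphereSasa <- function(centers, radius, probe, nPer = 1e5, seed = 42) {
  set.seed(seed)
  rExp <- radius + probe
  n <- nrow(centers)
  vapply(seq_len(n), function(i) {
    u <- matrix(rnorm(3 * nPer), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rExp, 2, centers[i, ], "+")
    free <- rep(TRUE, nPer)
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2 +
        (pts[, 3] - centers[j, 3])^2
      free <- free & d2 >= rExp^2
    }
    4 * pi * rExp^2 * mean(free)
  }, 1)
}

# closed-form log-linear rate oracle: ln Y = ln Y0 - k t
logLinearK <- function(timeMs, y) {
  ts <- timeMs / 1000
  -unname(coef(lm(log(y) ~ ts))[2])
}

# minimal rates table builder (ratesTableSchema layout)
makeRatesTable <- function(k, site = "A:1", residues = "W", peptide = "pep1",
                           modMass = 16, timesMs = c(0, 1, 2, 5, 10, 15),
                           replicates = 1, total = 1e6) {
  grid <- expand.grid(t = timesMs, rep = seq_len(replicates))
  y <- exp(-k * grid$t / 1000)
  data.frame(peptide_id = peptide, site = site, residues = residues,
             mod_mass = modMass, time_ms = grid$t,
             area_unmod = total * y, area_mod = total * (1 - y),
             replicate = paste0("r", grid$rep), stringsAsFactors = FALSE)
}
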