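# Shared fixture builders: everything is generated in code at test time.

# collection from a list of per-individual genotype vectors, e.g.
# list(c(101,101, 105,107), c(101,103, 105,105))
make_collection <- function(genos, river = "TST", year = 2010L) {
  collection(river, year, do.call(rbind, genos))
}

# two-allele collection with given genotype counts at a single locus
one_locus_collection <- function(n_aa = 0, n_ab = 0, n_bb = 0,
                                 a = 101L, b = 103L, river = "TST") {
  g <- rbind(matrix(a, n_aa, 2), cbind(rep(a, n_ab), rep(b, n_ab)),
             matrix(b, n_bb, 2))
  collection(river, 2010L, g)
}

# HWE genotypes at one locus from allele frequencies p
hwe_collection <- function(n, p, codes = 100L + 2L * seq_along(p),
                           river = "HWE") {
  g1 <- sample(codes, n, replace = TRUE, prob = p)
  g2 <- sample(codes, n, replace = TRUE, prob = p)
  collection(river, 2010L, cbind(g1, g2))
}

# small GENEPOP file text: pops is a list of lists of genotype strings
write_genepop_text <- function(path, loci, pops) {
  lines <- c("test file", loci)
  for (p in seq_along(pops)) {
    lines <- c(lines, "POP")
    for (i in seq_along(pops[[p]]))
      lines <- c(lines, paste0("P", p, "_2010_", i, " , ", pops[[p]][i]))
  }
  writeLines(lines, path)
}

# independent Dijkstra oracle on an ocean grid (8-neighbour, great-circle
# step weights), used to verify the igraph-based path engine
dijkstra_oracle <- function(grid, src_ij, dst_ij) {
  nr <- nrow(grid$mask); nc <- ncol(grid$mask)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[src_ij[1], src_ij[2]] <- 0
  repeat {
    d <- dist; d[done | !grid$mask] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
    done[ui, uj] <- TRUE
    if (ui == dst_ij[1] && uj == dst_ij[2]) break
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- ui + di; vj <- uj + dj
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (!grid$mask[vi, vj] || done[vi, vj]) next
      p1 <- cbind(grid$lon_origin + (uj - 1) * grid$cell,
                  grid$lat_origin + (ui - 1) * grid$cell)
      p2 <- cbind(grid$lon_origin + (vj - 1) * grid$cell,
                  grid$lat_origin + (vi - 1) * grid$cell)
      w <- geosphere::distHaversine(p1, p2) / 1000
      if (dist[ui, uj] + w < dist[vi, vj]) dist[vi, vj] <- dist[ui, uj] + w
    }
  }
  dist[dst_ij[1], dst_ij[2]]
}
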