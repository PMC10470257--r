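# Reference objects shared across tests: the published Kondepudi-Nelson
# matrices (typed in from the execution examples) and small constructors.

kn_network <- function() load_fixture("Kondepudi-Nelson")

# 9 x 12 extreme currents matrix of the plain KN stoichiometric matrix,
# column order as published.
kn_printed_E_plain <- function() {
  rows <- c("100010001010",
            "010000101100",
            "101000000000",
            "010100000000",
            "001001000101",
            "000100010011",
            "000011000000",
            "000000110000",
            "000000001111")
  t(vapply(rows, function(r) as.integer(strsplit(r, "")[[1]]),
           integer(12)))
}

# 9 x 6 extreme currents matrix of the extended KN matrix, as published.
kn_printed_E_ext <- function() {
  rows <- c("101010", "101010", "110000", "110000",
            "010101", "010101", "001100", "001100", "000011")
  t(vapply(rows, function(r) as.integer(strsplit(r, "")[[1]]),
           integer(6)))
}

jvar <- function(i) sp_var(paste0("j", i))
kvar <- function(i) sp_var(paste0("k", i))
xvar <- function(i) sp_var(paste0("x", i))

sum_j <- function(idx, coefs = rep(1, length(idx))) {
  acc <- sp_zero()
  for (i in seq_along(idx))
    acc <- sp_add(acc, sp_scale(jvar(idx[i]), coefs[i]))
  acc
}

# Columns of two nonnegative integer matrices equal as sets?
same_column_set <- function(A, B) {
  if (!all(dim(A) == dim(B))) return(FALSE)
  key <- function(M) sort(apply(M, 2, paste, collapse = ","))
  identical(key(A), key(B))
}

# Exact brute-force extreme-ray oracle: enumerate column supports in
# increasing size, keep supports whose restricted kernel is 1-dimensional
# with a strictly one-signed generator, pruning supersets of found
# supports (support-minimality).  Entries are small integers, so plain
# double arithmetic in the rref is exact.
oracle_extreme_rays <- function(S) {
  n <- ncol(S)
  kernel1 <- function(A) {
    m <- nrow(A); nc <- ncol(A)
    M <- matrix(as.numeric(A), m, nc)
    piv <- integer(0); r <- 1L
    for (cc in seq_len(nc)) {
      if (r > m) break
      p <- which(abs(M[r:m, cc]) > 1e-9)
      if (!length(p)) next
      p <- p[1] + r - 1L
      M[c(r, p), ] <- M[c(p, r), ]
      M[r, ] <- M[r, ] / M[r, cc]
      for (i in seq_len(m))
        if (i != r && abs(M[i, cc]) > 1e-12) M[i, ] <- M[i, ] - M[i, cc] * M[r, ]
      piv <- c(piv, cc); r <- r + 1L
    }
    free <- setdiff(seq_len(nc), piv)
    if (length(free) != 1L) return(NULL)
    v <- numeric(nc); v[free] <- 1
    for (ri in seq_along(piv)) v[piv[ri]] <- -M[ri, free]
    v
  }
  found_supports <- list()
  rays <- list()
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      skip <- FALSE
      for (f in found_supports) if (all(f %in% idx)) { skip <- TRUE; break }
      if (skip) next
      v <- kernel1(S[, idx, drop = FALSE])
      if (is.null(v)) next
      if (all(v > 1e-9) || all(v < -1e-9)) {
        if (all(v < 0)) v <- -v
        full <- numeric(n); full[idx] <- v
        # normalize to coprime integers (entries are small rationals)
        full <- full / min(full[full > 0])
        for (mult in 1:64) {
          if (max(abs(full * mult - round(full * mult))) < 1e-7) {
            full <- round(full * mult); break
          }
        }
        g <- Reduce(function(a, b) if (b == 0) a else
          chiralstab:::rat_gcd(a, b), full, accumulate = FALSE)
        found_supports[[length(found_supports) + 1L]] <- idx
        rays[[length(rays) + 1L]] <- full / max(g, 1)
      }
    }
  }
  if (!length(rays)) return(matrix(0L, n, 0L))
  E <- do.call(cbind, rays)
  storage.mode(E) <- "integer"
  E
}

# Printed-index -> consistent-index renumbering of the first-algorithm
# execution example (the published Jacobian example renumbers decay and
# decomposition constants relative to the parsed velocity vector).
kn_alg1_index_map <- c("0" = 0, "1" = 2, "2" = 2, "3" = 3, "4" = 4,
                       "5" = 6, "6" = 5, "7" = 7, "8" = 8)
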