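#' Duplex energy model parameters
#'
#' A reduced nearest-neighbor model for intermolecular RNA:RNA duplexes:
#' duplex initiation costs +4.1 kcal/mol, each stack of two adjacent base
#' pairs contributes `-(s(p) + s(q))/2` where the pair strengths are
#' `s(GC) = 3.3`, `s(AU) = 2.1`, `s(GU) = 1.0`, and every bulge or internal
#' loop between consecutive pairs costs +4.0 to open plus +0.5 per
#' unpaired nucleotide. Watson-Crick and G:U pairs are admissible.
#' Dangling ends are free. The model is a documented simplification of
#' full nearest-neighbor hybridization tables; its purpose is ordering
#' duplexes, not reproducing absolute published energies.
#'
#' @return named list with `init`, `loop_open`, `loop_ext` and the
#'   `pair_strength` table.
#' @export
duplex_energy_params <- function() {
  list(init = 4.1, loop_open = 4.0, loop_ext = 0.5,
       pair_strength = c(AU = 2.1, UA = 2.1, GC = 3.3, CG = 3.3,
                         GU = 1.0, UG = 1.0))
}

# strength of the base pair x:y, NA when inadmissible
pair_strength <- function(x, y) {
  ps <- duplex_energy_params()$pair_strength
  unname(ps[paste0(x, y)])
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Dynamic programming over intermolecular duplexes only (no intramolecular
#' structure). Both sequences are given 5' to 3' and hybridize antiparallel;
#' the optimal set of non-crossing base pairs under the
#' [duplex_energy_params()] model is returned together with its energy.
#' When no pairing achieves negative energy the result is `mfe = 0` with an
#' empty pairing (an unpaired duplex is always available).
#'
#' @param mirna_seq miRNA sequence, 5' to 3'.
#' @param target_seq target window, 5' to 3', at most 60 nt (quadratic DP
#'   guard; both sequences are checked).
#' @return list with `mfe` (kcal/mol) and `pairing`, a data.frame of
#'   (`mirna_pos`, `target_pos`) 1-based base pairs ordered 5' to 3' along
#'   the miRNA (and therefore 3' to 5' along the target).
#' @export
duplex_mfe <- function(mirna_seq, target_seq) {
  a <- normalize_rna(mirna_seq, "miRNA")
  b <- normalize_rna(target_seq, "target window")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (nchar(a) > 60L || nchar(b) > 60L) {
    stop("sequence longer than 60 nt (duplex DP guard)", call. = FALSE)
  }
  par <- duplex_energy_params()
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  Brev <- rev(strsplit(b, "", fixed = TRUE)[[1L]])  # align antiparallel
  n <- length(A); m <- length(Brev)
  strengths <- outer(seq_len(n), seq_len(m),
                     function(i, j) pair_strength(A[i], Brev[j]))
  E <- matrix(Inf, n, m)        # best energy of duplex ending in pair (i,j)
  choice <- matrix(0L, n, m)    # 0 = first pair, 1 = stack, 2 = gap
  # prefix minima of E[i',j'] - 0.5*(i'+j') over i'<i, j'<j, with argmins
  M <- matrix(Inf, n + 1L, m + 1L)
  Mi <- matrix(0L, n + 1L, m + 1L)
  Mj <- matrix(0L, n + 1L, m + 1L)
  gi <- matrix(0L, n, m)
  gj <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- M[i, j + 1L]; ci <- Mi[i, j + 1L]; cj <- Mj[i, j + 1L]
      if (M[i + 1L, j] < cand) {
        cand <- M[i + 1L, j]; ci <- Mi[i + 1L, j]; cj <- Mj[i + 1L, j]
      }
      prev <- if (i > 1L && j > 1L) {
        E[i - 1L, j - 1L] - par$loop_ext * ((i - 1L) + (j - 1L))
      } else Inf
      if (prev < cand) {
        cand <- prev; ci <- i - 1L; cj <- j - 1L
      }
      M[i + 1L, j + 1L] <- cand
      Mi[i + 1L, j + 1L] <- ci
      Mj[i + 1L, j + 1L] <- cj
      s <- strengths[i, j]
      if (is.na(s)) next
      best <- par$init                          # (i, j) opens the duplex
      ch <- 0L
      if (i > 1L && j > 1L && is.finite(E[i - 1L, j - 1L]) &&
          !is.na(strengths[i - 1L, j - 1L])) {
        stack <- E[i - 1L, j - 1L] -
          (strengths[i - 1L, j - 1L] + s) / 2
        if (stack < best) { best <- stack; ch <- 1L }
      }
      if (is.finite(cand)) {
        gap <- cand + par$loop_open - 2 * par$loop_ext +
          par$loop_ext * (i + j)
        if (gap < best) {
          best <- gap; ch <- 2L
          gi[i, j] <- ci; gj[i, j] <- cj
        }
      }
      E[i, j] <- best
      choice[i, j] <- ch
    }
  }
  empty <- data.frame(mirna_pos = integer(0), target_pos = integer(0))
  if (!any(is.finite(E)) || min(E) >= 0) {
    return(list(mfe = 0, pairing = empty))
  }
  idx <- which(E == min(E), arr.ind = TRUE)[1L, ]
  pairs <- list()
  i <- idx[[1L]]; j <- idx[[2L]]
  repeat {
    pairs[[length(pairs) + 1L]] <- c(i, j)
    ch <- choice[i, j]
    if (ch == 0L) break
    if (ch == 1L) { i <- i - 1L; j <- j - 1L }
    else { i2 <- gi[i, j]; j2 <- gj[i, j]; i <- i2; j <- j2 }
  }
  pairs <- do.call(rbind, rev(pairs))
  list(mfe = min(E),
       pairing = data.frame(mirna_pos = pairs[, 1L],
                            target_pos = m - pairs[, 2L] + 1L,
                            row.names = NULL))
}
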