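# Independent oracles, deliberately implemented with none of the package's
# alignment machinery: plain R loops and exhaustive dynamic programs.

# --- brute-force primer-pair scanner: test every offset, both orientations ---
oracle_match_primer_pair <- function(seq, fwd, rev, search_space) {
  occurs_in_window <- function(s, pat, from_start) {
    n <- nchar(s); k <- nchar(pat)
    win <- if (from_start) substr(s, 1, min(search_space, n))
           else substr(s, max(1, n - search_space + 1), n)
    if (nchar(win) < k) return(FALSE)
    for (off in 0:(nchar(win) - k))
      if (substr(win, off + 1, off + k) == pat) return(TRUE)
    FALSE
  }
  rc <- function(x) ccscluster::revcomp(x)
  if (occurs_in_window(seq, fwd, TRUE) &&
      occurs_in_window(seq, rc(rev), FALSE)) return("sense")
  flipped <- rc(seq)
  if (occurs_in_window(flipped, fwd, TRUE) &&
      occurs_in_window(flipped, rc(rev), FALSE)) return("antisense")
  NA_character_
}

# --- exhaustive ungapped all-offsets dovetail scan (substitution-only cases) ---
oracle_best_dovetail <- function(a, b) {
  # b shifted right of a's start by off (off >= 0); overlap = suffix(a)/prefix(b)
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  for (off in 0:(la - 1)) {
    olen <- min(la - off, lb)
    if (olen < 1) next
    av <- substr(a, off + 1, off + olen)
    bv <- substr(b, 1, olen)
    m <- sum(strsplit(av, "")[[1]] == strsplit(bv, "")[[1]])
    if (is.null(best) || m > best$matches)
      best <- list(offset = off, overlap_len = olen, matches = m,
                   identity = m / olen)
  }
  best
}

# --- Smith-Waterman with affine gaps (match +1, mismatch -2, open 5, ext 2) ---
oracle_local_align <- function(q, t) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0  # local: free start
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- ptrM; ptrY <- ptrM
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qc[i - 1] == tc[j - 1]) 1 else -2
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      w <- which.max(prev)
      M[i, j] <- prev[w] + s; ptrM[i, j] <- w
      gx <- c(M[i - 1, j] - 7, Ix[i - 1, j] - 2)
      wx <- which.max(gx); Ix[i, j] <- gx[wx]; ptrX[i, j] <- wx
      gy <- c(M[i, j - 1] - 7, Iy[i, j - 1] - 2)
      wy <- which.max(gy); Iy[i, j] <- gy[wy]; ptrY[i, j] <- wy
    }
  }
  sc <- max(M)
  if (sc <= 0)
    return(list(score = 0, n_match = 0L, n_mismatch = 0L,
                ins_bases = 0L, del_bases = 0L))
  hit <- which(M == sc, arr.ind = TRUE)[1, ]
  i <- hit[1]; j <- hit[2]
  state <- 1L
  nm <- 0L; nx <- 0L; ins <- 0L; del <- 0L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      if (ptrM[i, j] == 0L) break  # reached the zero boundary
      if (qc[i - 1] == tc[j - 1]) nm <- nm + 1L else nx <- nx + 1L
      state <- ptrM[i, j]
      i <- i - 1; j <- j - 1
      if (state == 4L) break
    } else if (state == 2L) {
      ins <- ins + 1L
      state <- if (ptrX[i, j] == 1L) 1L else 2L
      i <- i - 1
    } else {
      del <- del + 1L
      state <- if (ptrY[i, j] == 1L) 1L else 3L
      j <- j - 1
    }
  }
  list(score = sc, n_match = nm, n_mismatch = nx,
       ins_bases = ins, del_bases = del)
}

# --- exhaustive 3-sequence multiple alignment (sum-of-pairs, unit costs) ---
# returns the column-majority consensus of the optimal alignment, with the
# same calling rules as the CCS builder: gap wins on strict majority (column
# dropped), base ties break A<C<G<T
oracle_msa3_consensus <- function(s1, s2, s3) {
  ss <- list(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]], strsplit(s3, "")[[1]])
  n <- vapply(ss, length, integer(1))
  col_cost <- function(x) { # x: 3 symbols, NA = gap
    cost <- 0
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- x[p[1]]; b <- x[p[2]]
      cost <- cost + if (is.na(a) && is.na(b)) 0
        else if (is.na(a) || is.na(b)) 1
        else if (a == b) 0 else 1
    }
    cost
  }
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, , drop = FALSE]
  D <- array(Inf, dim = n + 1)
  P <- array(0L, dim = n + 1)
  D[1, 1, 1] <- 0
  for (i in 0:n[1]) for (j in 0:n[2]) for (k in 0:n[3]) {
    if (i + j + k == 0) next
    best <- Inf; bm <- 0L
    for (mi in seq_len(nrow(moves))) {
      mv <- moves[mi, ]
      pi <- c(i, j, k) - mv
      if (any(pi < 0)) next
      sym <- c(if (mv[1]) ss[[1]][i] else NA,
               if (mv[2]) ss[[2]][j] else NA,
               if (mv[3]) ss[[3]][k] else NA)
      cand <- D[pi[1] + 1, pi[2] + 1, pi[3] + 1] + col_cost(sym)
      if (cand < best) { best <- cand; bm <- mi }
    }
    D[i + 1, j + 1, k + 1] <- best
    P[i + 1, j + 1, k + 1] <- bm
  }
  # traceback -> columns -> consensus
  pos <- n
  cols <- list()
  while (sum(pos) > 0) {
    mv <- moves[P[pos[1] + 1, pos[2] + 1, pos[3] + 1], ]
    sym <- c(if (mv[1]) ss[[1]][pos[1]] else NA,
             if (mv[2]) ss[[2]][pos[2]] else NA,
             if (mv[3]) ss[[3]][pos[3]] else NA)
    cols[[length(cols) + 1]] <- sym
    pos <- pos - mv
  }
  cols <- rev(cols)
  out <- character(0)
  for (cl in cols) {
    gaps <- sum(is.na(cl))
    if (2 * gaps > 3) next       # strict gap majority: drop column
    bases <- cl[!is.na(cl)]
    tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
    if (gaps >= 2) next          # 2 gaps of 3 is also a strict majority
    out <- c(out, names(tab)[which.max(tab)])
  }
  paste(out, collapse = "")
}
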