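# Independent oracles and tiny fixture builders used across test files.
# Oracles are deliberately naive implementations kept separate from the
# package's code paths.

# quick annotation builder: all vectors recycled to n genes on one contig
mk_ann <- function(n, secreted = FALSE, family = NA_character_,
                   cds = "ATGTAA", protein_length = 100L, category = "core",
                   cysteines = 0L, expanded = FALSE, contig = "c1",
                   strand = "+") {
  ids <- sprintf("g%03d", seq_len(n))
  cds <- rep_len(cds, n)
  w <- nchar(cds)
  contig <- rep_len(contig, n)
  # per-contig sequential coordinates
  start <- integer(n); end <- integer(n)
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    e <- cumsum(w[i] + 10L)
    start[i] <- e - w[i] + 1L
    end[i] <- e
  }
  genes <- data.frame(gene_id = ids, contig = contig, start = start,
                      end = end, strand = rep_len(strand, n), cds = cds,
                      protein = strrep("M", pmax(1, w %/% 3 - 1)),
                      stringsAsFactors = FALSE)
  flags <- data.frame(gene_id = ids,
                      secreted = rep_len(secreted, n),
                      protein_length = rep_len(as.integer(protein_length), n),
                      cysteines = rep_len(as.integer(cysteines), n),
                      family_id = rep_len(family, n),
                      category = rep_len(category, n),
                      orphan = FALSE, pfam_families = "",
                      expanded_family = rep_len(expanded, n),
                      qvalue = NA_real_, stringsAsFactors = FALSE)
  genome_annotation(genes, flags)
}

# hand dinucleotide counter over a character vector walk
oracle_dinuc <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  out <- setNames(integer(16),
                  as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0)))
  if (length(ch) >= 2) {
    for (i in seq_len(length(ch) - 1)) {
      d <- paste0(ch[i], ch[i + 1])
      if (d %in% names(out)) out[d] <- out[d] + 1L
    }
  }
  out
}

# exhaustive hypergeometric upper tail: P(X >= h) drawing k from N with K marked
oracle_hyper_tail <- function(h, K, N, k) {
  xs <- max(0, h):min(k, K)
  sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}

# Gotoh affine global alignment; gap of length L costs open + L * ext.
# Maximises score, then matches among co-optimal alignments.
oracle_align <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  # state matrices: score and best matches at that score
  M <- matrix(NEG, n + 1, m + 1); Mm <- matrix(0L, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1); Xm <- matrix(0L, n + 1, m + 1) # gap in b
  Y <- matrix(NEG, n + 1, m + 1); Ym <- matrix(0L, n + 1, m + 1) # gap in a
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  pickmax <- function(scores, matches) {
    s <- max(scores)
    list(s = s, m = max(matches[scores == s]))
  }
  if (n > 0 && m > 0) {
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      sub <- if (A[i - 1] == B[j - 1]) match else mismatch
      inc <- as.integer(A[i - 1] == B[j - 1])
      p <- pickmax(c(M[i-1, j-1], X[i-1, j-1], Y[i-1, j-1]),
                   c(Mm[i-1, j-1], Xm[i-1, j-1], Ym[i-1, j-1]))
      M[i, j] <- p$s + sub; Mm[i, j] <- p$m + inc
      p <- pickmax(c(M[i-1, j] - open - ext, X[i-1, j] - ext),
                   c(Mm[i-1, j], Xm[i-1, j]))
      X[i, j] <- p$s; Xm[i, j] <- p$m
      p <- pickmax(c(M[i, j-1] - open - ext, Y[i, j-1] - ext),
                   c(Mm[i, j-1], Ym[i, j-1]))
      Y[i, j] <- p$s; Ym[i, j] <- p$m
    }
  }
  fin <- pickmax(c(M[n+1, m+1], X[n+1, m+1], Y[n+1, m+1]),
                 c(Mm[n+1, m+1], Xm[n+1, m+1], Ym[n+1, m+1]))
  list(score = fin$s, matches = fin$m)
}

# brute-force secreted-cluster finder: enumerate all windows, keep maximal
# valid ones (>= 3 secreted, ends secreted, never two adjacent non-secreted)
oracle_clusters <- function(secreted) {
  n <- length(secreted)
  valid <- list()
  for (i in seq_len(n)) for (j in i:n) {
    s <- secreted[i:j]
    if (!s[1] || !s[length(s)] || sum(s) < 3) next
    if (length(s) > 1 && any(!s[-length(s)] & !s[-1])) next
    valid[[length(valid) + 1L]] <- c(i, j)
  }
  if (length(valid) == 0) return(list())
  keep <- Filter(function(w) !any(vapply(valid, function(v)
    (v[1] < w[1] && v[2] >= w[2]) || (v[1] <= w[1] && v[2] > w[2]),
    logical(1))), valid)
  lapply(keep, function(w) seq(w[1], w[2]))
}

# random DNA string with its own seed (same base sequence across RIP rates)
rand_seq_seeded <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, rand_seq(n, gc))
}

# random DNA string helper
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1-gc)/2, gc/2, gc/2, (1-gc)/2)), collapse = "")
}
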