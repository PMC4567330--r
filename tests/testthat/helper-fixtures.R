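# Shared fixtures and independent oracles, all built in code.

# regular-grid design: probe i starts at (i-1)*spacing, width `width`
grid_design <- function(n = 100L, spacing = 100L, width = 60L,
                        chrom = "chr1", platform = "toy") {
  genome <- data.frame(chrom = chrom, length = n * spacing)
  probe_design(platform, data.frame(chrom = chrom,
                                    start = (seq_len(n) - 1L) * spacing,
                                    end = (seq_len(n) - 1L) * spacing + width),
               genome)
}

# profile from raw values; marked centralized so detection does not warn
toy_profile <- function(values, design = grid_design(length(values)),
                        sample_id = "S1", intensity = NULL) {
  p <- array_profile(sample_id, design, values, intensity = intensity)
  p$state$centralized <- TRUE
  p
}

# O(n^2) brute-force maximum interval score, independent of the package path
brute_max_interval <- function(x, sigma) {
  n <- length(x)
  best <- list(score = -1, from = NA, to = NA)
  ps <- c(0, cumsum(x))
  for (i in seq_len(n)) for (j in i:n) {
    s <- abs(ps[j + 1] - ps[i]) / sqrt(j - i + 1) / sigma
    if (s > best$score) best <- list(score = s, from = i, to = j)
  }
  best
}

# same brute force, vectorized per start (for larger property sweeps);
# tie-breaking matches: leftmost start, then shortest interval
brute_max_interval_vec <- function(x, sigma) {
  n <- length(x)
  ps <- c(0, cumsum(x))
  best <- -1; bi <- NA; bj <- NA
  for (i in seq_len(n)) {
    lens <- seq_len(n - i + 1)
    s <- abs(ps[i + lens] - ps[i]) / sqrt(lens)
    j <- which.max(s)
    if (s[j] > best) { best <- s[j]; bi <- i; bj <- i + j - 1L }
  }
  list(score = best / sigma, from = bi, to = bj)
}

# exhaustive Poisson-binomial tail by enumerating all 2^S outcomes
enum_pb_tail <- function(g, k) {
  S <- length(g)
  total <- 0
  for (mask in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(S)]
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1, g, 1 - g))
  }
  total
}

# independent transitive closure via boolean matrix powering
closure_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# brute-force MCR oracle: group CNARs by any-overlap closure, intersect all
# member segments, apply platform and non-emptiness rules
oracle_mcr <- function(cnars_by_platform, n_cohort,
                       require_platforms = names(cnars_by_platform)) {
  flat <- list()
  for (pf in names(cnars_by_platform))
    for (r in cnars_by_platform[[pf]]) { r$platform <- pf; flat[[length(flat) + 1L]] <- r }
  if (!length(flat)) return(list())
  key <- paste(vapply(flat, `[[`, "", "chrom"), vapply(flat, `[[`, "", "direction"))
  out <- list()
  for (k in unique(key)) {
    grp <- flat[key == k]
    m <- length(grp)
    adj <- matrix(FALSE, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      ov <- min(grp[[i]]$end, grp[[j]]$end) - max(grp[[i]]$start, grp[[j]]$start)
      adj[i, j] <- ov > 0
    }
    comp <- closure_components(adj)
    for (cid in unique(comp)) {
      mem <- grp[comp == cid]
      pf <- unique(vapply(mem, `[[`, "", "platform"))
      if (!all(require_platforms %in% pf)) next
      segs <- do.call(rbind, lapply(mem, `[[`, "members"))
      s <- max(segs$start); e <- min(segs$end)
      if (e <= s) next
      out[[length(out) + 1L]] <- list(
        chrom = mem[[1]]$chrom, start = s, end = e,
        direction = mem[[1]]$direction,
        samples = sort(unique(segs$sample_id)))
    }
  }
  ord <- order(vapply(out, `[[`, "", "chrom"), vapply(out, `[[`, 0, "start"))
  out[ord]
}

# random CNAR lists over platforms for the MCR oracle comparison
random_cnar_instance <- function(n_platforms = 3L, max_loci = 3L) {
  platforms <- paste0("pf", seq_len(n_platforms))
  loci <- sample.int(max_loci, 1L)
  centers <- sort(sample.int(1e6, loci)) * 10
  out <- setNames(vector("list", n_platforms), platforms)
  sid <- 0L
  for (pf in platforms) {
    cnars <- list()
    for (lc in seq_len(loci)) {
      if (runif(1) < 0.3) next  # platform misses this locus
      k <- sample(2:4, 1L)
      starts <- centers[lc] + sample(-5000:5000, k, replace = TRUE)
      lens <- sample(2000:20000, k, replace = TRUE)
      sid <- sid + k
      members <- data.frame(sample_id = sprintf("S%04d", sid - seq_len(k)),
                            chrom = "chr1", start = starts,
                            end = starts + lens,
                            stringsAsFactors = FALSE)
      cnars[[length(cnars) + 1L]] <- structure(list(
        kind = "CNAR", chrom = "chr1",
        start = min(members$start), end = max(members$end),
        direction = "gain", members = members,
        samples = unique(members$sample_id),
        n_support = length(unique(members$sample_id)),
        frequency = NA, platforms = pf), class = "RecurrentRegion")
    }
    out[[pf]] <- cnars
  }
  out
}

# two-sided Fisher p by hypergeometric enumeration (fisher.test convention:
# sum probabilities of tables at most as likely as the observed one)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
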