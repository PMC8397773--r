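# Independent brute-force oracles.  These deliberately share no code with
# the implementation: plain loops over instances, pairs and paths.

# classical Simple Ratio Index on a toy record set, ignoring lifespans:
# loops over every realized (night, logger) instance
oracle_classical_sri <- function(records, ids, window,
                                 night_start = 18, night_end = 6) {
  lt <- as.POSIXlt(records$timestamp, tz = "UTC")
  night <- as.Date(lt) - ifelse(lt$hour >= night_start, 0, 1)
  minute <- ifelse(lt$hour >= night_start,
                   (lt$hour - night_start) * 60 + lt$min,
                   (24 - night_start + lt$hour) * 60 + lt$min)
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      A <- ids[a]; B <- ids[b]
      x <- yab <- ya <- yb <- 0
      for (nt in unique(night)) {
        in_night <- night == nt
        obs_A_night <- any(in_night & records$individual_id == A)
        obs_B_night <- any(in_night & records$individual_id == B)
        for (lg in unique(records$logger_id[in_night])) {
          here <- in_night & records$logger_id == lg
          tA <- minute[here & records$individual_id == A]
          tB <- minute[here & records$individual_id == B]
          if (length(tA) && length(tB)) {
            gaps <- abs(outer(tA, tB, "-"))
            if (min(gaps) <= window) x <- x + 1 else yab <- yab + 1
          } else if (length(tA)) {
            if (obs_B_night) yab <- yab + 1 else ya <- ya + 1
          } else if (length(tB)) {
            if (obs_A_night) yab <- yab + 1 else yb <- yb + 1
          }
        }
      }
      denom <- x + yab + ya + yb
      out[a, b] <- out[b, a] <- if (denom > 0) x / denom else 0
    }
  }
  out
}

oracle_jaccard <- function(c1, c2) {
  s1 <- which(c1 > 0); s2 <- which(c2 > 0)
  un <- union(s1, s2)
  if (!length(un)) return(0)
  length(intersect(s1, s2)) / length(un)
}

oracle_bray <- function(p1, p2) {
  1 - 2 * sum(pmin(p1, p2)) / (sum(p1) + sum(p2))
}

oracle_chao1 <- function(x) {
  x <- x[x > 0]
  s <- length(x); f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

# exhaustive shortest-path betweenness: enumerate every simple path between
# every ordered pair by depth-first search over a distance matrix
oracle_betweenness <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(node, visited, len) {
      if (node == to) {
        paths[[length(paths) + 1]] <<- list(path = visited, len = len)
        return()
      }
      for (nxt in seq_len(n)) {
        if (is.finite(d[node, nxt]) && !(nxt %in% visited)) {
          walk(nxt, c(visited, nxt), len + d[node, nxt])
        }
      }
    }
    walk(from, from, 0)
    paths
  }
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t <= s) next
      ps <- all_paths(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      short <- ps[abs(lens - min(lens)) < 1e-12]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        onpath <- sum(vapply(short, function(p) v %in% p$path, logical(1)))
        btw[v] <- btw[v] + onpath / length(short)
      }
    }
  }
  btw
}

# information centrality via resistance distances from the Moore-Penrose
# pseudoinverse of the weighted Laplacian (a route independent of the
# implementation's (L + J) inverse)
oracle_information <- function(w) {
  n <- nrow(w)
  L <- diag(rowSums(w)) - w
  Lp <- MASS::ginv(L)
  r <- outer(diag(Lp), diag(Lp), "+") - 2 * Lp
  n / rowSums(r)
}

oracle_mantel_r <- function(m1, m2) {
  cor(m1[upper.tri(m1)], m2[upper.tri(m2)])
}

# direct normal-equation OLS for the MRQAP worked example
oracle_ols <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))
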