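# Independent brute-force oracles. These re-derive every quantity by naive
# enumeration, sharing no code with the package internals beyond the input
# tables themselves.

oracle_joint_arrivals <- function(arrivals, ids, start_date, end_date,
                                  max_gap_min = 5, max_party = 4) {
  # earliest arrival per individual-day, scanning row by row
  a <- arrivals[arrivals$individual_id %in% ids &
                  arrivals$date >= start_date & arrivals$date < end_date, ]
  firsts <- list()
  for (i in seq_len(nrow(a))) {
    k <- paste(a$individual_id[i], a$date[i])
    if (is.null(firsts[[k]]) || a$time_min[i] < firsts[[k]]$time_min) {
      firsts[[k]] <- a[i, ]
    }
  }
  fa <- do.call(rbind, firsts)
  counts <- setNames(rep(0L, length(ids)), ids)
  pairs <- list()
  if (!is.null(fa)) {
    qa <- fa[fa$party_size_at_arrival <= max_party, ]
    for (id in ids) counts[id] <- sum(qa$individual_id == id)
    if (nrow(qa) >= 2) {
      for (i in seq_len(nrow(qa) - 1)) {
        for (j in (i + 1):nrow(qa)) {
          if (qa$date[i] != qa$date[j]) next
          if (qa$individual_id[i] == qa$individual_id[j]) next
          if (abs(qa$time_min[i] - qa$time_min[j]) > max_gap_min) next
          key <- paste(sort(c(qa$individual_id[i], qa$individual_id[j])),
                       collapse = "|")
          pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  list(counts = counts, joint = pairs)
}

oracle_sri <- function(joint, n_a, n_b) {
  den <- n_a + n_b - joint
  if (den <= 0) return(NA_real_)
  joint / den
}

oracle_strong <- function(values) {
  values > mean(values)
}

# all 15+ per-male measures recomputed naively from a dyad-metrics table
oracle_male_measures <- function(dm, male, focal_male_min = NA) {
  rows_of <- dm[dm$id_a == male | dm$id_b == male, ]
  pass_a <- dm[dm$passes_assoc, ]
  pass_r <- dm[dm$passes_groom & !is.na(dm$groom_rate), ]
  pass_c <- dm[!is.na(dm$csi), ]
  my_a <- rows_of[rows_of$passes_assoc, ]
  my_r <- rows_of[rows_of$passes_groom & !is.na(rows_of$groom_rate), ]
  my_c <- rows_of[!is.na(rows_of$csi), ]
  m_sri <- mean(pass_a$sri, na.rm = TRUE)
  m_joint <- mean(pass_a$joint)
  m_time <- mean(pass_a$groom_min)
  m_rate <- mean(pass_r$groom_rate)
  m_csi <- mean(pass_c$csi)
  sri <- my_a$sri[!is.na(my_a$sri)]
  top3 <- sort(my_c$csi, decreasing = TRUE)
  top3 <- top3[seq_len(min(3, length(top3)))]
  list(
    n_assoc_ties = sum(sri > 0),
    sum_sri_all = sum(sri),
    n_strong_assoc_ties = sum(sri > m_sri),
    sum_sri_strong = sum(sri[sri > m_sri]),
    n_strong_raw_ties = sum(my_a$joint > m_joint),
    sum_raw_strong = sum(my_a$joint[my_a$joint > m_joint]),
    groom_total_min = sum(my_a$groom_min),
    groom_rate_overall = if (!is.na(focal_male_min) && focal_male_min > 0)
      sum(my_a$groom_min) / focal_male_min else 0,
    n_groom_partners = sum(my_a$groom_min > 0),
    n_strong_groom_time_ties = sum(my_a$groom_min > m_time),
    sum_groom_time_strong = sum(my_a$groom_min[my_a$groom_min > m_time]),
    mean_groom_rate = if (nrow(my_r)) mean(my_r$groom_rate) else 0,
    n_strong_groom_rate_ties = sum(my_r$groom_rate > m_rate),
    sum_groom_rate_strong = sum(my_r$groom_rate[my_r$groom_rate > m_rate]),
    sum_top3_csi = sum(top3),
    n_strong_csi_ties = sum(my_c$csi > m_csi),
    sum_strong_csi = sum(my_c$csi[my_c$csi > m_csi])
  )
}

oracle_dyadize <- function(coalitions) {
  out <- list()
  for (i in seq_len(nrow(coalitions))) {
    actors <- sort(strsplit(coalitions$actor_ids[i], ";")[[1]])
    for (a in seq_along(actors)) {
      for (b in seq_along(actors)) {
        if (a < b) {
          out[[length(out) + 1]] <-
            data.frame(date = coalitions$date[i],
                       id_a = actors[a], id_b = actors[b])
        }
      }
    }
  }
  do.call(rbind, out)
}

# exhaustive geodesic-counting betweenness for small graphs (n <= ~8)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  # all shortest path lengths by BFS
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in 1:n) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (dist[s, w] > d) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  # enumerate all simple paths between s and t of geodesic length
  paths_between <- function(s, t) {
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        if (length(path) - 1 == dist[s, t]) res[[length(res) + 1]] <<- path
        return(invisible())
      }
      if (length(path) - 1 >= dist[s, t]) return(invisible())
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% path)) walk(c(path, w))
      }
    }
    walk(s)
    res
  }
  btw <- rep(0, n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(dist[s, t]) || dist[s, t] == 0) next
      ps <- paths_between(s, t)
      if (!length(ps)) next
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(ps, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / length(ps)
      }
    }
  }
  btw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
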