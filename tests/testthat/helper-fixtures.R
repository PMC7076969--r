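# shared fixtures: tiny maps and populations built in code

two_marker_map <- function(d_cM) {
  genetic_map("1", c("mA", "mB"), c(0, d_cM), c(1, 1e6))
}

small_map <- function(n_chr = 1, m = 11, len = 50) {
  synthetic_map(n_chr, m, len)
}

f1_haps <- function(map) rbind(rep(1L, nrow(map)), rep(2L, nrow(map)))

# brute-force oracle for interval narrowing: enumerate every elementary
# unit (marker point or open inter-marker gap) inside the interval and
# keep the units consistent with every verdict
oracle_narrow_units <- function(types, interval, map) {
  mk <- map$bp[map$bp >= interval[1] & map$bp <= interval[2]]
  units <- list()
  for (i in seq_along(mk)) {
    units[[length(units) + 1L]] <- c(mk[i], mk[i], 0)          # marker point
    if (i < length(mk)) units[[length(units) + 1L]] <- c(mk[i], mk[i + 1], 1)  # open gap
  }
  ok <- vapply(units, function(u) {
    for (r in seq_len(nrow(types))) {
      if (!types$valid[r] || is.na(types$verdict[r])) next
      if (types$verdict[r] == "S") {
        # unit must lie inside the possible heterozygous segment
        if (u[3] == 0) {
          if (u[1] < types$pos_lo_bp[r] || u[1] > types$pos_hi_bp[r]) return(FALSE)
        } else {
          if (u[1] < types$pos_lo_bp[r] || u[2] > types$pos_hi_bp[r]) return(FALSE)
        }
      } else {
        # unit must not intersect the certain heterozygous segment
        if (u[3] == 0) {
          if (u[1] >= types$het_lo_bp[r] && u[1] <= types$het_hi_bp[r]) return(FALSE)
        } else {
          if (u[2] > types$het_lo_bp[r] && u[1] < types$het_hi_bp[r]) return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
  do.call(rbind, units)[ok, , drop = FALSE]
}

# convert narrow_interval()'s raw candidate pieces to the same unit set
pieces_to_units <- function(pieces, interval, map) {
  mk <- map$bp[map$bp >= interval[1] & map$bp <= interval[2]]
  units <- list()
  for (i in seq_along(mk)) {
    units[[length(units) + 1L]] <- c(mk[i], mk[i], 0)
    if (i < length(mk)) units[[length(units) + 1L]] <- c(mk[i], mk[i + 1], 1)
  }
  inside <- vapply(units, function(u) {
    for (j in seq_len(nrow(pieces))) {
      p <- pieces[j, ]
      if (u[3] == 0) {
        lo_ok <- u[1] > p$lo || (u[1] == p$lo && !p$lo_open)
        hi_ok <- u[1] < p$hi || (u[1] == p$hi && !p$hi_open)
        if (lo_ok && hi_ok) return(TRUE)
      } else {
        if (u[1] >= p$lo && u[2] <= p$hi &&
            !(u[1] == p$lo && FALSE)) {
          # open gap (u1,u2): contained iff piece covers it (openness at
          # piece ends only matters at exact endpoints, which the open
          # gap does not include)
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  do.call(rbind, units)[inside, , drop = FALSE]
}

# random verdict-bearing type sets over an m-marker map
random_types <- function(map, n_types, seed_offset = 0) {
  m <- nrow(map)
  rows <- lapply(seq_len(n_types), function(k) {
    i <- sample.int(m, 1); j <- sample(i:m, 1)
    data.frame(type = as.character(utils::as.roman(k)),
               het_lo_bp = map$bp[i], het_hi_bp = map$bp[j],
               pos_lo_bp = map$bp[max(i - 1, 1)],
               pos_hi_bp = map$bp[min(j + 1, m)],
               valid = TRUE,
               verdict = sample(c("S", "NS"), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
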