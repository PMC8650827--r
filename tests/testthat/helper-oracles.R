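## Independent brute-force two-way sums of squares, computed from cell
## means with explicit formulas (valid for balanced designs). Used as the
## oracle against the aov-based implementation.
brute_force_ss <- function(value, a, b) {
  gm <- mean(value)
  la <- sort(unique(a)); lb <- sort(unique(b))
  n_cell <- length(value) / (length(la) * length(lb))
  ma <- vapply(la, function(x) mean(value[a == x]), numeric(1))
  mb <- vapply(lb, function(x) mean(value[b == x]), numeric(1))
  ss_a <- n_cell * length(lb) * sum((ma - gm)^2)
  ss_b <- n_cell * length(la) * sum((mb - gm)^2)
  ss_int <- 0; ss_res <- 0
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      sel <- a == la[i] & b == lb[j]
      mc <- mean(value[sel])
      ss_int <- ss_int + n_cell * (mc - ma[i] - mb[j] + gm)^2
      ss_res <- ss_res + sum((value[sel] - mc)^2)
    }
  }
  list(a = unname(ss_a), b = unname(ss_b), int = unname(ss_int),
       res = unname(ss_res), total = sum((value - gm)^2))
}

fake_results <- function(value, rep_f, net_f, repeat_i = seq_along(value)) {
  data.frame(representation = rep_f, network = net_f,
             repeat_index = repeat_i, accuracy = value, auroc = value,
             stringsAsFactors = FALSE)
}

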