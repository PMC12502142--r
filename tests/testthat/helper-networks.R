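ex <- example_networks()

# deterministic bundle of small random networks for the property suites
random_suite <- function(n_networks = 50L, n_min = 4L, n_max = 7L,
                         max_indegree = 3L, seed_base = 100L) {
  lapply(seq_len(n_networks), function(k) {
    n <- n_min + ((k - 1L) %% (n_max - n_min + 1L))
    random_network(n, max_indegree = min(max_indegree, n), seed = seed_base + k)
  })
}

dnf_of <- function(net, var) format_dnf_for_test(net$functions[[var]])

format_dnf_for_test <- function(dnf) {
  if (length(dnf) == 0L) return("0")
  if (any(vapply(dnf, length, 1L) == 0L)) return("1")
  cl <- vapply(dnf, function(clause) {
    ord <- order(names(clause))
    paste(ifelse(clause[ord] > 0L, names(clause)[ord],
                 paste0("!", names(clause)[ord])), collapse = "&")
  }, "")
  paste(sort(cl), collapse = " | ")
}
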