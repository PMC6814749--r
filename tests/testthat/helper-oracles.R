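# exhaustive enumeration oracle for the one-sided rank-sum p-value:
# all C(n1+n2, n1) assignments of the observed ranks to group 1
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(vals), n1)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(U_all >= U_obs - 1e-9)
}
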