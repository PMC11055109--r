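# Brute-force two-way within-subjects ANOVA: explicit sums-of-squares
# partition, the independent oracle for rm_anova().
brute_rm <- function(d) {
  subj <- levels(d$subject); trt <- levels(d$treatment); tim <- levels(d$time)
  n <- length(subj); a <- length(trt); b <- length(tim)
  y <- function(s, i, j) {
    d$value[d$subject == s & d$treatment == i & d$time == j]
  }
  grand <- mean(d$value)
  m_s <- sapply(subj, function(s) mean(d$value[d$subject == s]))
  m_i <- sapply(trt, function(i) mean(d$value[d$treatment == i]))
  m_j <- sapply(tim, function(j) mean(d$value[d$time == j]))
  ss_t <- n * b * sum((m_i - grand)^2)
  ss_b <- n * a * sum((m_j - grand)^2)
  ss_tb <- 0
  for (i in trt) for (j in tim) {
    m_ij <- mean(d$value[d$treatment == i & d$time == j])
    ss_tb <- ss_tb + n * (m_ij - m_i[i] - m_j[j] + grand)^2
  }
  ss_st <- 0
  for (s in subj) for (i in trt) {
    m_si <- mean(d$value[d$subject == s & d$treatment == i])
    ss_st <- ss_st + b * (m_si - m_s[s] - m_i[i] + grand)^2
  }
  ss_sb <- 0
  for (s in subj) for (j in tim) {
    m_sj <- mean(d$value[d$subject == s & d$time == j])
    ss_sb <- ss_sb + a * (m_sj - m_s[s] - m_j[j] + grand)^2
  }
  ss_stb <- 0
  for (s in subj) for (i in trt) for (j in tim) {
    m_si <- mean(d$value[d$subject == s & d$treatment == i])
    m_sj <- mean(d$value[d$subject == s & d$time == j])
    m_ij <- mean(d$value[d$treatment == i & d$time == j])
    ss_stb <- ss_stb +
      (y(s, i, j) - m_si - m_sj - m_ij + m_s[s] + m_i[i] + m_j[j] - grand)^2
  }
  list(
    F_treatment = unname((ss_t / (a - 1)) / (ss_st / ((n - 1) * (a - 1)))),
    F_time = unname((ss_b / (b - 1)) / (ss_sb / ((n - 1) * (b - 1)))),
    F_interaction = unname((ss_tb / ((a - 1) * (b - 1))) /
      (ss_stb / ((n - 1) * (a - 1) * (b - 1))))
  )
}
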