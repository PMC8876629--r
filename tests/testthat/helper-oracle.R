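# Independent oracles and shared fixtures.  The oracles decompose strings
# directly (no chart, no grammar object) so they stay independent of the
# code paths they check.

# the 19-nt worked example: sequence, parser-output row, final structure
WX_SEQ <- "CCAUCGCCUGAUUUGAGGA"
WX_CORE_DB <- "....[...(].....)..."
WX_FINAL_DB <- "..[[[.(((]]]...)))."
WX_CAND <- list(i1 = 5L, i2 = 9L, j1 = 10L, j2 = 16L)

ORACLE_BASES <- c("A", "U", "C", "G")
ORACLE_WC <- c(A = "U", U = "A", C = "G", G = "C")

# every decomposition x.l1.y.d.z.l2.w of s (|l1|,|l2| >= 1, 0 <= |d| <= max_dd,
# (x,z) and (y,w) Watson-Crick), by direct enumeration
oracle_splits <- function(s, max_dd = 2) {
  n <- nchar(s)
  u <- strsplit(s, "")[[1]]
  out <- list()
  if (n >= 6) {
    for (l1 in 1:(n - 5)) {
      py <- l1 + 2                       # 1-based position of y
      for (d in 0:max_dd) {
        pz <- py + 1 + d                 # 1-based position of z
        if (pz > n - 2) break
        if (identical(unname(ORACLE_WC[u[1]]), u[pz]) &&
            identical(unname(ORACLE_WC[u[py]]), u[n])) {
          rid <- 4L * (match(u[py], ORACLE_BASES) - 1L) +
            (match(u[1], ORACLE_BASES) - 1L)
          out[[length(out) + 1L]] <- c(rid, l1, d)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(rule_id = integer(0), l1_len = integer(0),
                      d_len = integer(0)))
  m <- do.call(rbind, out)
  res <- data.frame(rule_id = m[, 1], l1_len = m[, 2], d_len = m[, 3])
  res <- res[order(res$rule_id, res$l1_len, res$d_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_member <- function(s, max_dd = 2) nrow(oracle_splits(s, max_dd)) > 0

random_rna <- function(n) paste(sample(ORACLE_BASES, n, TRUE), collapse = "")

# all strings of length n over an alphabet
all_strings <- function(n, alphabet = c("A", "U")) {
  if (n == 0) return("")
  apply(do.call(expand.grid, rep(list(alphabet), n)), 1, paste,
        collapse = "")
}

# printed confusion rows of the benchmark tables (platform x length bin):
# tp, tn, fp, fn and the printed 3-decimal PPV/recall/F1/MCC
PRINTED_METRIC_ROWS <- read.csv(text = "
table,platform,tp,tn,fp,fn,ppv,recall,f1,mcc
all,IHFold,3056,3556,1968,2196,0.608,0.582,0.595,0.226
all,HotKnots,4180,3632,1744,1220,0.706,0.774,0.738,0.452
all,IPknot,3872,3767,1522,1615,0.718,0.706,0.712,0.418
all,Knotty,5026,3352,1870,528,0.729,0.905,0.807,0.569
all,yaep,4212,4102,1162,1300,0.784,0.764,0.774,0.543
all,bruteforce,4214,4101,1160,1301,0.784,0.764,0.774,0.543
lt30,IHFold,738,522,118,513,0.862,0.590,0.701,0.386
lt30,HotKnots,904,492,156,339,0.853,0.727,0.785,0.465
lt30,IPknot,916,514,124,337,0.881,0.731,0.799,0.510
lt30,Knotty,1196,469,146,80,0.891,0.937,0.914,0.722
lt30,yaep,1244,486,134,27,0.903,0.979,0.939,0.805
lt30,bruteforce,1242,485,136,28,0.901,0.978,0.938,0.802
30to40,IHFold,550,832,352,587,0.610,0.484,0.539,0.191
30to40,HotKnots,922,851,294,254,0.758,0.784,0.771,0.528
30to40,IPknot,824,823,314,360,0.724,0.696,0.710,0.420
30to40,Knotty,1078,802,324,117,0.769,0.902,0.830,0.628
30to40,yaep,988,893,296,144,0.769,0.873,0.818,0.627
30to40,bruteforce,988,893,296,144,0.769,0.873,0.818,0.627
40to50,IHFold,612,864,478,418,0.561,0.594,0.577,0.237
40to50,HotKnots,792,857,510,213,0.608,0.788,0.687,0.412
40to50,IPknot,764,911,410,287,0.651,0.727,0.687,0.414
40to50,Knotty,904,817,524,127,0.633,0.877,0.735,0.492
40to50,yaep,764,1010,298,300,0.719,0.718,0.719,0.490
40to50,bruteforce,772,1012,290,298,0.727,0.721,0.724,0.499
ge50,IHFold,1156,1338,1020,678,0.531,0.630,0.577,0.196
ge50,HotKnots,1562,1432,784,414,0.666,0.790,0.723,0.439
ge50,IPknot,1368,1519,674,631,0.670,0.684,0.677,0.377
ge50,Knotty,1848,1264,876,204,0.678,0.901,0.774,0.515
ge50,yaep,1216,1713,434,829,0.737,0.595,0.658,0.402
ge50,bruteforce,1212,1711,438,831,0.735,0.593,0.656,0.398
", stringsAsFactors = FALSE)

# 3-decimal round-half-up, matching the tables' convention
round3up <- function(x) floor(x * 1000 + 0.5) / 1000

# a varied, feasible plant spec for fixture k under a base seed; stems are
# at least 3 deep (2-deep stems rarely admit a unique maximal candidate, so
# shallow specs exhaust the generator's rejection budget by design)
varied_spec <- function(k, base_seed = 1L) {
  set.seed(base_seed * 1000L + k)
  plant_spec(stem1_len = sample(3:5, 1), stem2_len = sample(3:5, 1),
             loop1_len = sample(1:5, 1), loop2_len = sample(1:6, 1),
             gap_len = sample(0:2, 1), flank5_len = sample(0:5, 1),
             flank3_len = sample(0:5, 1),
             seed = base_seed * 100000L + k)
}
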