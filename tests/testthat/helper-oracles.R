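# Independent oracles used for cross-validation:
#  - brute-force two-way mean-squares via stats::aov
#  - pingouin (Python) ICC(A,1) and Cronbach alpha through a single
#    subprocess call over many datasets at once

# ICC(A,1) from an independent route: aov() two-way decomposition
aovICCOracle <- function(x, y) {
  n <- length(x)
  long <- data.frame(y = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     sess = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + sess, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

pythonBin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}

# Run pingouin over a list of paired datasets; returns a data.frame with
# icc, icc_p, alpha per dataset (full double precision via JSON).
pingouinOracle <- function(datasets) {
  stopifnot(nzchar(pythonBin()))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  inFile <- file.path(dir, "pairs.csv")
  outFile <- file.path(dir, "oracle.json")
  long <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    data.frame(set = i, subj = seq_along(d$x), x = d$x, y = d$y)
  }))
  utils::write.csv(format(long, digits = 17), inFile, row.names = FALSE)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import json, sys",
    "import pandas as pd, pingouin as pg",
    sprintf("d = pd.read_csv(%s)", deparse(inFile)),
    "out = []",
    "for s, g in d.groupby('set'):",
    "    long = pd.DataFrame({'subj': list(g.subj) * 2,",
    "                         'sess': ['s1'] * len(g) + ['s2'] * len(g),",
    "                         'v': list(g.x) + list(g.y)})",
    "    icc = pg.intraclass_corr(long, targets='subj', raters='sess',",
    "                             ratings='v')",
    "    row = icc[icc.Type == 'ICC(A,1)'].iloc[0]",
    "    a = pg.cronbach_alpha(data=pd.DataFrame({'s1': list(g.x),",
    "                                             's2': list(g.y)}))",
    "    out.append({'set': int(s), 'icc': float(row.ICC),",
    "                'icc_p': float(row.pval),",
    "                'ci_low': float(row.CI95[0]),",
    "                'ci_high': float(row.CI95[1]),",
    "                'alpha': float(a[0])})",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outFile))),
    script)
  status <- system2(pythonBin(), script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(outFile))
    stop("pingouin oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(outFile, simplifyVector = TRUE)
}
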