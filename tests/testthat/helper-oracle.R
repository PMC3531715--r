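# Independent NMF oracle: scikit-learn's NMF (multiplicative-update solver)
# run through the system Python. Used only to cross-check final Frobenius
# costs; it never stands in for the package's own implementation.

sklearn_nmf_best_costs <- function(mats, s, n_restarts = 20) {
  td <- tempfile("nmforacle")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  for (i in seq_along(mats))
    write.table(mats[[i]], file.path(td, sprintf("m%02d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  script <- file.path(td, "oracle.py")
  writeLines(c(
    "import sys, os, glob, json",
    "import numpy as np",
    "from sklearn.decomposition import NMF",
    "d, s, R = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])",
    "out = []",
    "for f in sorted(glob.glob(os.path.join(d, 'm*.csv'))):",
    "    X = np.loadtxt(f, delimiter=',')",
    "    best = np.inf",
    "    for r in range(R):",
    "        m = NMF(n_components=s, init='random', solver='mu',",
    "                beta_loss='frobenius', tol=1e-7, max_iter=3000,",
    "                random_state=r)",
    "        W = m.fit_transform(X)",
    "        c = float(np.linalg.norm(X - W @ m.components_))",
    "        best = min(best, c)",
    "    out.append(best)",
    "print(json.dumps(out))"
  ), script)
  py <- Sys.which("python")
  stopifnot(nzchar(py))
  res <- suppressWarnings(
    system2(py, c(script, td, s, n_restarts), stdout = TRUE, stderr = FALSE))
  as.numeric(jsonlite::fromJSON(res[length(res)]))
}
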