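#!/usr/bin/env Rscript
# Step 5 - the verification suite: analytic finite-element oracles (axial
# bar, patch test, cantilever vs beam theory, truss bar formula), the
# Boolean-vs-Monte-Carlo volume cross-check and the phantom specification
# recovery.  Exits non-zero if any check fails.

suppressMessages(library(lumbosim))

chk <- run_validation()
print(chk, digits = 4)
write.csv(chk, "results/validation.csv", row.names = FALSE)
if (!attr(chk, "ok")) {
  cat("VERIFICATION FAILED\n")
  quit(status = 1)
}
cat("all checks passed\n")
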