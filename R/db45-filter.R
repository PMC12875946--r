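# Daubechies-45 orthonormal scaling (lowpass decomposition) filter, length 90.
# Standard minimum-phase Daubechies construction (45 vanishing moments),
# computed by spectral factorization of the maximally-flat half-band
# polynomial at 200-digit precision and rounded to double.
# Invariants: sum(h) = sqrt(2), sum(h^2) = 1, even shifts orthonormal.
.db45_dec_lo <- c(
  1.10711506415074017e-21,
  -3.27321258352291967e-20,
  4.08180263123302209e-19,
  -2.54828588331459007e-18,
  5.23248292097516402e-18,
  3.57490556052491222e-17,
  -2.84159055456074271e-16,
  5.13034654704775875e-16,
  2.66986144556432998e-15,
  -1.55897010779402496e-14,
  1.07158863106500721e-14,
  1.48020309636985384e-13,
  -4.53817275619316311e-13,
  -4.18191483268088810e-13,
  4.73815311290355213e-12,
  -5.31008029171567408e-12,
  -2.61536575357058333e-11,
  7.83637051043263742e-11,
  5.29749518525699926e-11,
  -5.52092340608402607e-10,
  4.25367955427601329e-10,
  2.46323007192670007e-9,
  -5.09674845427349680e-9,
  -6.27165681568451597e-9,
  3.02557624695531111e-8,
  -3.09295196602137259e-9,
  -1.23915700810612817e-7,
  1.26629548894130179e-7,
  3.62654268519602677e-7,
  -7.68760921058347413e-7,
  -6.53410442680318841e-7,
  3.08932223944396270e-6,
  -1.68696810875766038e-7,
  -9.46704665893458463e-6,
  6.91684010035712303e-6,
  0.0000227017145527310441,
  -0.0000332810897843569115,
  -0.0000406756239896174808,
  0.000108957017229509692,
  0.0000411773740331221720,
  -0.000283193499320120272,
  0.0000475121358113538280,
  0.000612456077964940458,
  -0.000386998799191211502,
  -0.00111634963045819916,
  0.00126178887949725778,
  0.00169443141738003153,
  -0.00307200497676115793,
  -0.00202204633988201076,
  0.00625482949558125100,
  0.00147696444996119129,
  -0.0111356325511751383,
  0.000834465102425323755,
  0.0177653432243220962,
  -0.00590855298651527944,
  -0.0258471717416957574,
  0.0145586184204272620,
  0.0348521129221950504,
  -0.0271112598550341532,
  -0.0443543232361165209,
  0.0432000781585233997,
  0.0545181081963329258,
  -0.0616916246519496691,
  -0.0665980850504702618,
  0.0806061027297802600,
  0.0832966172340089658,
  -0.0966680470375919172,
  -0.108761955451225766,
  0.103873205720353025,
  0.147578734186241063,
  -0.0903220024373110874,
  -0.200526971002903623,
  0.0335543687759777479,
  0.250879878664572451,
  0.0982634829460692529,
  -0.230346226701702298,
  -0.301572623997561952,
  -0.0174241469118843350,
  0.342512296208588407,
  0.502998445449841050,
  0.433688779445161388,
  0.267574304293863571,
  0.125473846439725753,
  0.0456637382633923504,
  0.0129156582835561574,
  0.00280129967968395819,
  0.000452033249684058197,
  0.0000512849898773742052,
  3.65918223334343050e-6,
  1.23766350936090794e-7
)
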