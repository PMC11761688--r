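"id","frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]","offset [photon]","bkgstd [photon]","uncertainty [nm]"
1,1,1250.5,980.25,148.2,950.0,10.2,3.4,12.5
2,1,4820.0,3300.75,155.9,420.5,9.8,3.1,28.9
3,4,1252.1,978.9,150.4,1100.2,10.5,3.6,11.2
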