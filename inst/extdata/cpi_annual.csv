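"year","index"
2010,218.056
2011,224.939
2012,229.594
2013,232.957
2014,236.736
2015,237.017
2016,240.007
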