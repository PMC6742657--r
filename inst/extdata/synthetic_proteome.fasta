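>P00001 synthetic
MKCFINPVAGRKRSYGMIARHSTVTCESFWARYQDISNQDQHDARRFIWLVLNGG
>P00002 synthetic
MKCLNYQTQDIQWTTMHRGQARHLFGSMENQWHKHCARSPWYRHEAIYSMARSYIDEYNTLYMIQTCMPQGARINEPSSAIILIVKHHLMGG
>P00003 synthetic
MKAWLPMMYHYKKFQQGALTTHARKYGVTFYDQACELAARFIPVLGHKSTPIHYVTARACTCPTDVCFNPLGLLGG
>P00004 synthetic
MKGSSDEDDSCRYKHKECNARKMHPFMAWNCTNDVARRDWVTGLILPYGYYKSIHARLTVIWLMTNCWPPWLSFEVARASTNCVNRWGSRGG
>P00005 synthetic
MKWDQAASMENPLLHVARTYKMNIVFVSLKARMGNWEDQIGELSSYLGWEARKERYTHRFQRRSWARIFHYSSKMMWLCGYQQGG
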