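STATIONS_ID;MESS_DATUM;QN_3;  FX;  FM;QN_4; RSK;RSKF; SDK;SHK_TAG;  NM; VPM;  PM; TMK; UPM; TXK; TNK; TGK;eor
4349;20091220;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091221;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091222;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091223;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091224;   10;   0;   0;   3; 0.0;   0; 0.0;   -999;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091225;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091226;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091227;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091228;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091229;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091230;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20091231;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100101;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100102;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100103;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100104;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100105;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100106;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100107;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100108;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100109;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100110;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100111;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100112;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100113;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100114;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100115;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
4349;20100116;   10;   0;   0;   3; 0.0;   0; 0.0;      0;   5; 5.0; 990;-1.0;  85; 1.0;-3.0;-4.0;eor
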