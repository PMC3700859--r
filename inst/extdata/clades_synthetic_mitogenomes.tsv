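sample_id	population	region	coverage	variants
U5b1f_01	Guipuzcoa	Spanish Basque Country	complete_genome	150 3010 4218 5215 5656 9477 11467 12308 14182 16192 16270 16320 16519
U5b1f_02	Guipuzcoa	Spanish Basque Country	complete_genome	150 3010 4218 5656 8701 9477 11467 12308 14182 16192 16270 16320
U5b1f_03	Biscay	Spanish Basque Country	complete_genome	150 4218 5656 6365 9477 11467 12308 12634 14182 16192 16270 16320
U5b1f_04	Biscay	Spanish Basque Country	complete_genome	150 4218 5656 6365 9477 11467 12308 14182 15218 16192 16270 16320
U5b1f_05	Northern Navarre	Spanish Basque Country	complete_genome	150 1719 2857 4218 5656 9477 11467 12308 14182 16192 16270 16320
U5b1f_06	Northern Navarre	Spanish Basque Country	complete_genome	150 1719 4218 5656 9477 10400 11467 12308 14182 16192 16270 16320
U5b1f_07	Iparralde	French Basque Country	complete_genome	150 4218 5656 7028 9477 11467 12308 14182 16192 16270 16320
U5b1f_08	Iparralde	French Basque Country	complete_genome	150 4218 5656 8860 9477 11467 12308 14182 16192 16270 16320
U5b1f_09	Alava	Spanish Basque Country	complete_genome	150 4218 5656 9477 11467 12308 13617 14182 16192 16270 16320
U5b1f_10	Northern Navarre	Spanish Basque Country	complete_genome	150 4218 5656 9477 11467 12308 14182 15326 16192 16270 16320
U5b1f_11	Guipuzcoa	Spanish Basque Country	complete_genome	150 204 4218 5656 9477 11467 12308 14182 16093 16192 16270 16320
U5b1f_12	Iparralde	French Basque Country	complete_genome	150 4218 5656 9477 11467 12308 14182 16192 16270 16320
J1c5c1_01	Guipuzcoa	Spanish Basque Country	complete_genome	185 222 482 3394 5460 9632 14798 16069 16126 16145
J1c5c1_02	Northern Navarre	Spanish Basque Country	complete_genome	185 222 309.1C 482 5460 7476 9632 14798 16069 16126 16145 16519
J1c5c1_03	Biscay	Spanish Basque Country	complete_genome	185 222 482 5460 9632 11002 14798 16069 16126 16145
J1c5c1_04	Iparralde	French Basque Country	complete_genome	185 222 482 5460 9632 14798 16069 16126 16145 16172
J1c5c1_05	Northern Navarre	Spanish Basque Country	complete_genome	185 222 482 5460 9632 14798 16069 16126 16145
J1c5c1_06	Alava	Spanish Basque Country	complete_genome	185 222 482 5460 9632 14798 16069 16126 16145
J1c5c1_07	Pas Valley	Cantabria	complete_genome	185 222 482 5460 9632 14798 16069 16126 16145
V22_01	Guipuzcoa	Spanish Basque Country	complete_genome	150 3027 4580 7765 9948 15671 16298
V22_02	Biscay	Spanish Basque Country	complete_genome	150 4580 7765 9948 11914 15671 16298
V22_03	Biscay	Spanish Basque Country	complete_genome	150 4580 5046 7765 15671 16183 16298
V22_04	Northern Navarre	Spanish Basque Country	complete_genome	150 4580 6776 7765 15671 16298
V22_05	Northern Navarre	Spanish Basque Country	complete_genome	150 4580 7765 8251 15671 16298
V22_06	Iparralde	French Basque Country	complete_genome	150 4580 7765 10238 15671 16298
V22_07	Alava	Spanish Basque Country	complete_genome	150 4580 7765 13708 15671 16298
V22_08	Pas Valley	Cantabria	complete_genome	150 4580 7765 15671 16256 16298
V22_09	Guipuzcoa	Spanish Basque Country	complete_genome	150 1811 4580 7765 15671 16298 16362
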