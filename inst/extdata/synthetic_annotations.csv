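class_id,start,end
SynM,2017-11-01 06:05:57,2017-11-01 06:09:25
SynM,2017-11-01 06:16:21,2017-11-01 06:20:27
SynM,2017-11-01 06:34:26,2017-11-01 06:35:24
SynM,2017-11-01 06:40:15,2017-11-01 06:45:18
SynM,2017-11-01 07:28:53,2017-11-01 07:31:00
SynM,2017-11-01 07:37:31,2017-11-01 07:39:37
SynM,2017-11-01 07:46:45,2017-11-01 07:48:38
SynM,2017-11-01 08:19:19,2017-11-01 08:23:17
SynM,2017-11-01 08:27:51,2017-11-01 08:29:53
SynM,2017-11-01 08:35:51,2017-11-01 08:37:39
SynX,2017-11-01 10:03:12,2017-11-01 10:07:29
SynM,2017-11-01 10:37:55,2017-11-01 10:42:02
SynA,2017-11-01 12:56:29,2017-11-01 12:58:33
SynA,2017-11-01 13:07:16,2017-11-01 13:10:13
SynA,2017-11-01 13:57:55,2017-11-01 14:00:15
SynA,2017-11-01 15:00:16,2017-11-01 15:03:11
SynA,2017-11-01 15:12:39,2017-11-01 15:15:40
SynX,2017-11-01 15:26:47,2017-11-01 15:31:43
SynA,2017-11-01 16:21:47,2017-11-01 16:24:00
SynA,2017-11-01 16:41:13,2017-11-01 16:42:53
SynE,2017-11-01 19:12:17,2017-11-01 19:17:27
SynE,2017-11-01 19:32:49,2017-11-01 19:33:57
SynE,2017-11-01 20:31:24,2017-11-01 20:33:33
SynE,2017-11-01 22:30:11,2017-11-01 22:33:59
SynE,2017-11-01 22:59:14,2017-11-01 23:04:13
SynE,2017-11-01 23:11:27,2017-11-01 23:15:36
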